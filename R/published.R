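## Loaders for the published summary tables of the barley TaDREB3
## experiment, shipped as plain TSV transcriptions under
## inst/extdata/published.  Numeric columns that the package recomputes
## (normalized counts, log2 ratios, fractions) are kept as printed strings
## so agreement can be checked at the table's own precision.

publishedPath <- function(file) {
  f <- system.file("extdata", "published", file, package = "sRNAcascade",
                   mustWork = TRUE)
  f
}

readPublished <- function(file, character = TRUE) {
  ## header comment lines start with '#'; cells may legitimately contain
  ## '#' (the "#NUM!" sentinel), so comment.char cannot be used
  lines <- readLines(publishedPath(file))
  lines <- lines[!startsWith(lines, "#")]
  read.delim(text = lines, check.names = FALSE,
             colClasses = if (character) "character" else NA)
}

#' Published tables of the emulated experiment
#'
#' Returns the transcribed summary tables of the published barley TaDREB3
#' small-RNA experiment: per-group size distributions at read-count
#' thresholds 1/4/10, the group comparison statistics for the chloroplast
#' and non-chloroplast streams, the known-miRNA profile, the novel-miRNA
#' candidate table (with hairpin MFE values), and the degradome validation
#' tags.  Derived columns are strings exactly as printed.
#'
#' @return named list of data.frames: `sizeControl`, `sizeTransgenic`,
#'   `groupStats`, `knownMirna`, `novelMirna`, `degradome`.
#' @export
publishedTables <- function() {
  list(sizeControl = readPublished("size_distribution_control.tsv"),
       sizeTransgenic = readPublished("size_distribution_transgenic.tsv"),
       groupStats = readPublished("group_statistics.tsv"),
       knownMirna = readPublished("known_mirna.tsv"),
       novelMirna = readPublished("novel_mirna.tsv"),
       degradome = readPublished("degradome_tags.tsv"))
}

## Agreement at the printed precision: |computed - printed| within half a
## unit in the last printed decimal place (and at least 6 significant
## decimals for long-format cells).
agreesWithPrinted <- function(computed, printed) {
  printed <- trimws(printed)
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^-?[0-9]*\\.", "", printed)), 0L)
  abs(computed - as.numeric(printed)) <= 0.5 * 10^(-dec) + 1e-12
}

#' Recompute every derived column of the published tables
#'
#' From the printed raw integers alone, recomputes the normalization
#' factor, every normalized count and finite log2 ratio of the known- and
#' novel-miRNA tables, the group-specificity of the zero-count rows, all
#' ratio/percentage fields of the group statistics, the column totals of
#' both size-distribution tables, the -18 kcal/mol verdict of every
#' printed hairpin MFE, and the cleavage position of every printed
#' degradome tag — and reports cell-level agreement with the printed
#' values at their own precision.
#'
#' @return data.frame with one row per checked cell: `table`, `check`,
#'   `computed`, `printed`, `agree`.
#' @export
verifyPublishedTables <- function() {
  tb <- publishedTables()
  rows <- list()
  add <- function(table, check, computed, printed,
                  agree = agreesWithPrinted(computed, printed)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, check = check, computed = as.character(computed),
      printed = as.character(printed), agree = agree)
  }

  ## size distributions: per-column sums against printed totals
  for (nm in c("sizeControl", "sizeTransgenic")) {
    x <- tb[[nm]]
    body <- x$length != "total"
    for (col in setdiff(names(x), "length")) {
      s <- sum(as.numeric(x[[col]][body]))
      add(nm, paste0(col, "_total"), s, x[[col]][!body], agree =
            s == as.numeric(x[[col]][!body]))
    }
  }

  ## group statistics: all printed ratio/percentage fields
  g <- tb$groupStats
  num <- function(col) as.numeric(g[[col]])
  for (i in seq_len(nrow(g))) {
    id <- sprintf("%s_t%s", g$stream[i], g$threshold[i])
    add("groupStats", paste0(id, "_unique_fraction"),
        num("unique_ctrl")[i] / num("unique_tg")[i], g$unique_fraction[i])
    add("groupStats", paste0(id, "_count_fraction"),
        num("count_ctrl")[i] / num("count_tg")[i], g$count_fraction[i])
    add("groupStats", paste0(id, "_specific_fraction"),
        num("specific_ctrl")[i] / num("specific_tg")[i],
        g$specific_fraction[i])
    add("groupStats", paste0(id, "_de_percent"),
        100 * num("de_sum")[i] / num("common")[i], g$de_percent[i])
  }

  ## normalization factor from the non-chloroplast totals (threshold 1)
  t1 <- g[g$stream == "non_chloroplast" & g$threshold == "1", ]
  fac <- normalizationFactor(as.numeric(t1$count_ctrl),
                             as.numeric(t1$count_tg))
  add("groupStats", "normalization_factor_2dp", round(fac@value, 2), "1.38",
      agree = round(fac@value, 2) == 1.38)

  ## known/novel miRNA tables: normalized and log2 cells
  checkDE <- function(x, label) {
    for (i in seq_len(nrow(x))) {
      ca <- as.numeric(x$count_ctrl[i])
      cb <- as.numeric(x$count_tg[i])
      nb <- normalizeCount(cb, fac)
      add(label, paste0(x$mirna[i], "_normalized"), nb, x$normalized_tg[i])
      if (x$log2[i] == "#NUM!") {
        cls <- deClassify(ca, cb, fac)
        add(label, paste0(x$mirna[i], "_specific"),
            as.character(cls), "A-specific",
            agree = cls %in% c("A-specific", "B-specific"))
      } else {
        add(label, paste0(x$mirna[i], "_log2"),
            suppressWarnings(log2Ratio(ca, nb)), x$log2[i])
      }
    }
  }
  known <- tb$knownMirna
  checkDE(known[known$is_star == "0", ], "knownMirna")
  checkDE(tb$novelMirna, "novelMirna")

  ## MFE filter on the printed hairpin energies (strict -18 rule)
  mfes <- as.numeric(tb$novelMirna$mfe)
  flt <- filterCandidates(data.frame(sequence = tb$novelMirna$sequence,
                                     mfe = mfes))
  add("novelMirna", "mfe_filter_pass_count", sum(flt$verdict == "pass"),
      nrow(tb$novelMirna), agree = all(flt$verdict == "pass"))

  ## degradome: printed tags against the p/p+1 convention (slack <= 1)
  dg <- tb$degradome
  for (i in seq_len(nrow(dg))) {
    cl <- callCleavage(dg$tag[i], dg$mirna_sequence[i])
    add("degradome", sprintf("%s_tag%d", dg$mirna[i], i),
        if (is.null(cl)) "none" else cl$position, dg$position[i],
        agree = !is.null(cl) && cl$position == dg$position[i])
  }

  `rownames<-`(do.call(rbind, rows), NULL)
}
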