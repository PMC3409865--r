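# Published degradome (PARE) validation tags for the novel miRNA candidates.
# position: printed cleavage-site label p/p+1 (cleavage between the target nucleotides
# pairing miRNA positions p and p+1, counted from the miRNA 5' end).
# accessions: transcripts containing the tag ("NA" where none was available).
# The novel-candidate table prints "Hv-miRX28" for the candidate this table
# calls Hvu-miRX18 (same sequence); the X18 name is used consistently here.
mirna	mirna_sequence	position	tag	accessions
Hvu-miRX1	GAATGACGCCGGGTCCGAAAG	10/11	AGGCGTCATTCAAATTTCTG	NA
Hvu-miRX2	AGTGACGCGCATGAATGGATT	10/11	GCGCGTCACTGCAACGGATAA	NA
Hvu-miRX2	AGTGACGCGCATGAATGGATT	10/11	GCGCGTCACTAATTAGATGAC	BY864760/BY865136/BY859056/BY865253/BY861299/BY839718/TC275169/BY864507/TC281249/AL508349/BI951089/TC279957/AJ432484/AU252321/TC281472/BI949016/TC281181/TC281158/TC257287/TC257303/BI953026/TC262239/TC278355/TC261623/TC268219/TC275184/TC274467/TC273938/TC268772
Hvu-miRX2	AGTGACGCGCATGAATGGATT	12/13	ATGCGCGTCACTAATTAGATG	NA
Hvu-miRX2	AGTGACGCGCATGAATGGATT	13/14	CATGCGCGTCACTAATTAGAT	NA
Hvu-miRX3	TGCTCACTGCTCTATCTGTCACC	10/11	GCAGTGAGCAGCCGGGTTAA	NA
Hvu-miRX4	AGGTGTCATCCCGCCTGAACA	10/11	GATGACACCTTTAGAGCGGG	dbj|AK356860.1|
Hvu-miRX5	ACTGGTTGGATCATGCTTCTC	10/11	TCCAACCAGTCAGATCCAACCA	NA
Hvu-miRX5	ACTGGTTGGATCATGCTTCTC	10/11	TCCAACCAGTCCGACGATCCAA	NA
Hvu-miRX5	ACTGGTTGGATCATGCTTCTC	11/12	ATCCAACCAGTCCGACGATCCA	NA
Hvu-miRX5	ACTGGTTGGATCATGCTTCTC	12/13	GATCCAACCAGTCCGACGATCC	NA
Hvu-miRX6	ATTTACTTGTAGAAGAAGCTA	10/11	ACAAGTAAATACGACATGGG	gb|HQ825319.1|/gb|AF147501.1|
Hvu-miRX7	TCAGATGAGAAGGCAGATCATA	10/11	TCTCATCTGAGTTTGATCCT	NA
Hvu-miRX7	TCAGATGAGAAGGCAGATCATA	10/11	TCTCATCTGAAATATGATCCT	NA
Hvu-miRX8	TAGGAAAGTAGAGTAGGCACA	11/12	CTACTTTCCTACAAAGTTAT	NA
Hvu-miRX9	ATTGACGACCTAGATACACGTGCA	12/13	TAGGTCGTCAATCCTACCAT	NA
Hvu-miRX10	TCTGTAACTTAATATAAGACG	14/15	TATTAAGTTACAGAGGGAGAG	NA
Hvu-miRX11	TATTTGCAGGTTTTAGGTCTAA	10/11	CCTGCAAATAATATAGCATGT	NA
Hvu-miRX11	TATTTGCAGGTTTTAGGTCTAA	10/11	CCTGCAAATACCTGGTTCTC	NA
Hvu-miRX12	AATTATTTAGGTACAGAGGGA	10/11	CTAAATAATTTAAAAATGGA	NA
Hvu-miRX13	AATTAATATGGATCGGAGGGA	10/11	CATATTAATTTCGACAACCC	NA
Hvu-miRX14	CCGAACTGATGGAAAGGGCTA	10/11	ATCAGTTCGGCAGAGAGCAGA	NA
Hvu-miRX15	TTTTGGTTGCGTTGGCTAGTGCAT	10/11	GCAACCAAAAGTCCGAACTAA	CA023038
Hvu-miRX16	TATAGTAATGATGGCTAATGGT	10/11	CATTACTATACCTTCCCTATT	gb|EF115541.1|/emb|X14108.1|/gb|M35616.1|/BLYCPPSBEF/gb|M35977.1|/BLYCPBEF/TC276030
Hvu-miRX17	TTAGGATTAGGAATAGGTGTA	10/11	CTAATCCTAAGGATTCCTTAA	NA
Hvu-miRX18	AAATAGAATAATGATCAACGGA	10/11	TATTCTATTTCACTATTTCA	BE437950/gb|EF115541.1|
Hvu-miRX18	AAATAGAATAATGATCAACGGA	10/11	TATTCTATTTTTGTTGGATC	NA
Hvu-miRX19	TTTGAGGGTTCTAGTCTTTGC	10/11	GTGTAGAACCCTCAAATGAG	NA
Hvu-miRX20	ATCGTATGAACTTGAAGCAACGGT	10/11	TTCATACGATCCAACGAGTTC	NA
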