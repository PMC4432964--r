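#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
SYNPROT1             -            130 TOYFAM               -            120   5.2e-57  177.5  12.7   1   1   6.4e-57   6.4e-57  177.2  12.7    32   120    22   110     4   110 0.92 synthetic protein with N-truncated toy domain
#
# Program:         hmmsearch
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SEARCH
# Query file:      toyfam.hmm
# Target file:     target.fa
# Option settings: hmmsearch --domtblout scan.domtblout toyfam.hmm target.fa 
# Current dir:     /root/pkg/scratch
# Date:            Sat Sep 19 07:52:07 2026
# [ok]
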