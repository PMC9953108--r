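#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
PAS                  PF00989.25   110 P1                   -            350   1.2e-20   70.5   0.1   1   2   1.0e-22   2.1e-18   65.3   0.1     3   108     8   112    10   110 0.95 PAS domain
HisKA                PF00512.25    66 P1                   -            350   4.0e-15   52.0   0.0   2   2   3.3e-17   6.6e-13   48.1   0.0     1    66   150   215   148   216 0.97 His Kinase A domain
Response_reg         PF00072.24   112 P2                   -            130   9.9e-30  100.2   0.0   1   1   8.0e-32   1.6e-27   93.4   0.0     2   111     12   125    11   126 0.98 Response regulator
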