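LOCUS       SYNPL01               153 bp    DNA     linear   SYN 01-JAN-2013
DEFINITION  synthetic plastome fragment carrying a trnF-like gene (test
            fixture; not a natural sequence).
ACCESSION   SYNPL01
SOURCE      synthetic construct
  ORGANISM  synthetic construct
FEATURES             Location/Qualifiers
     source          1..153
                     /organism="synthetic construct"
     tRNA            41..113
                     /gene="trnF"
                     /product="tRNA-Phe"
ORIGIN
        1 ccagttgatg tgcatccatt caccattctg ggtgagaact gccgggatag ctcagttggt
       61 agagcaggac tctgaaatag tccagggtcg tgggttcaaa tcccactccc ggcttactcc
      121 tctattgagt aattcgtcaa ggaaaataga tta
//
LOCUS       SYNPL02                64 bp    DNA     linear   SYN 01-JAN-2013
DEFINITION  synthetic background fragment without features (test fixture).
ACCESSION   SYNPL02
SOURCE      synthetic construct
  ORGANISM  synthetic construct
FEATURES             Location/Qualifiers
     source          1..64
                     /organism="synthetic construct"
ORIGIN
        1 tattgtaaaa taaccgatgt taatccggta tggtttattg ttttgtccag cttcctgagt
       61 aatg
//
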