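# synthetic ESE hexamer set: 84 seeded uniform draws from the 4096 hexamers
# stands in for an intersection-based ESE catalogue; not a real ESE list
AAACCG
AACAAA
ACATGG
ACCAGG
ACCCTC
ACCGTT
ACGCGC
ACGCGG
ACGTCC
ACGTGG
ACTCCT
AGATGC
AGGCAC
AGGTCC
AGGTCG
ATACAG
ATCCGT
ATGAAC
ATTTAT
ATTTTA
CACGAG
CAGACC
CAGAGG
CAGGGT
CATCGA
CATGTC
CCAAGT
CCCGAT
CCGGCT
CCGTGA
CCGTTG
CCTCAC
CCTCCA
CCTGGG
CTAATC
CTCATA
CTCCAG
CTCGAC
CTCTTG
CTTCAT
CTTCGA
GAAGCA
GACAAA
GACAGC
GACCCC
GACGTA
GACTTG
GAGCTC
GATGGT
GATGTT
GATTTT
GCAAAG
GCAAGT
GCCACT
GCCCGA
GCCCGG
GCTCCA
GCTTGT
GGAAGG
GGAAGT
GGATCG
GGATTC
GGCTAC
GTGAAA
GTTAGC
GTTCTT
GTTGGA
GTTGGG
TAACAA
TACATG
TAGATA
TAGTAT
TCAAAT
TCGCAC
TCGGCC
TCGGTA
TGAGTT
TGATCA
TGGACG
TGGAGA
TGTGCA
TGTTAG
TTCTTG
TTGCCC
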