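>chrT
GAATGATCAGAGACATTATATTAATATAAGCAGAGTATGTTCTTAACTTACGCATGAACATCGTTAGTGA
CTGCAGATACACACACGCAACGATTTCTGTACTAAAGAAGTCATAAGAACTAGATATTATTGAACAATGT
GTTGCAAGAAAACTGATGCAATCAATATTACGTCAGCACTAACGTACAATTAACTTAGAACGTCTGACAG
AAAACGAAATAGAGTCGAAATATTCGCAACATCAGTCTAAGTTGTAGCAGTGCAGATGAGTTAAGACGAA
GAGACTAACGACGCAGATATTTGTCAGTGCAGACACTTGACTACAGCGTGTGACACATTGTTAACATTTT
GCAAGCAATGAACAGACAGCGACTGAGAAAGCTTCGAAATCGTAAGACTAATGATAATTGCTTGTATTCT
AACTATTTTCATGTCTCTCATTAATGAGTTGGTAGGTTAGGATGGTGATTGTATGCGACAGTTTCAGATG
TGAGATCATCTGAATATGCGATTTCTTCTGACGCAGTATTAATACACTAAGATCTACTGACAGAATTCAT
GCATATTGAATGAAAACTTGCGAACAGATTCTTTTATCTCTGTGAACGACATAGCGAGAAATTGCTCAAC
ATACAGAGATCGATTCATCTGACATAGTCAATTAATACACGCTTAGACGCGAGTTGGTATGGATGGTTAG
ATAACTAGATTGAAACATAGCTAGACAACTCTAATGAAGAGAGAGTACACTAGAATTACAGTGCATGCTA
ACGATAAGAGACAAACGTTTAAGATGCGATCTGCACTCACACAGCAGAAGAAATGCAAGATTCGCAGCTG
CAGCAGAGTACAATAGAGTTTTCTCGTACGACTAAGAGCTGAGATTATGAAACTTGATATGACAGATCAT
GAGACAGACTGCACATGCATGTAAACACATTCACACAAATCTTACAACAAGACATCAACTCGCACAAGAA
CTGAAACGATTGAAATTGATCGATTCATTTTCGTAGTCAAGACGTGTGCGATAAGCTTATAACAAGTTAC
GCAAGATACAGTATCATAGACGACATTTGAGCATCAGAACTCTTTAGTACAAGTGATGATCGACAGATCA
TACGAGTGTGAGTAGATTGTCGAGCGCACTGAGAGAGAGTTCACGAGTCGAGTGAATTATTGTACTGTAT
TGAATTACATCTTATCGATATGTTTAACAAGTAACTTCTTACTGAAGAGACAAAAAGTGTCTTCGAGATG
ACAAGAGCATTGATGATATTGAATCGAGACACTTTCATTTGAGATGAAGCAGAACACAAGAGTATCAAAG
AAGTAGTGACAATTACTAATGTACAAATGACTAGTAAATCGCATAAACGTGAACAAAGAGAGATCACAAT
CAATGTGAGATCGAGAAGTAGAGTGTCGTCTGTGCGAACACAAACGATCAATACTAGATCTAGTCACAGC
ATATCTTAGAGTGATGTCGAATTATCAGACGTTAGATATTACAACACGATTATGAGTCGAGTTTTAGAGC
AAAGATCTTTCAATCAACAAGTTCAAAAGAAACACAAGACACACACAATAAGAATCAAGAACTAAGATGA
TTCAGTTCACTAGTCTTACAACGATTACACAGTCTGCTAAGAGTTTTCACTACGTGTAAAAAAATTATCA
GATACAATGCGATCTTTCTTCATGATTAACGCTTGCGAAAATCGATTTGAGAATTCGTGCTGTCAATAGT
AGTAGACAACGCAGACATTGCGAAGTACAACAGCGATTCGCTATAATATCGATATACACAGTTTCAATAC
ATTCGCAATCACAGTATACATATTTGACGAAGACGATACGATGCATAAGTACTCTCTTCATCATATTCTC
GCACGTTCAATGAGTTCATCTTAGAGTCATATAGTATCAGATCGTATTAACGATTAGTCAGAGAATTCTC
AGTTTATAAAAAGCAAGAACAGTAAGTTGACAAAGAGTCACACTCATTCGACGTTCTAGCAAGTAGAATC
ATTTTATTATTCTGATGATTTTGACTACACAGTAGATTCGTTTTCGTTGAAAGTTAACTTACACTCTCGA
CGTATAGTCTAATCGCACAGCACTACGATGACAGATGAGACAATCACATAAGACTTGACATTAGTTCGAA
TCAGCAGATCATGCATTACACACAGCATGCATCGACAGAAGAATCAAGATTTTCACTGTGTACGCTAGAA
ATCAGACGTAGACGAACACATAGTTATGAATACACAATAAATGATCAGTCATCAGTTTCTGAATGCGAGC
AGATTCAACTACAGCAAGATTTTGATATGTTACTTATGTAGACACACACATGTACATAGTGCAACAGTGT
AGTCGTCGAGATTGAGTGAGATGTTGTACTACGTGTAGTACTACAGCTCGTATGATTTTGCAGTTTCGCA
TAGAATATAATGAGCAGATTCAGAGATGCTTCTACAAAAGCACGCGACGTACTGTACATCGTGATCATTC
TAAGTACTAAACATTTAAAGCGCATTAAATAGAGTTCGTCAAAGAGTTAACATACTACTGAGATTATCGC
GACAACACGAAAACAAGCTTGCACTTGCTCAAAACGAGACAAACTTGTTGATACTAAACAAAAACAGAAC
TTAACTCAGACTCTTTGTTTATGATACATCACGACGAAAGTCGATGCAAAACTAGCATCATAAAATAAGA
ACTAATTAGTCGTCAAAGAGTTCGATCATCTGTAGCAGATGATATTCAAATTGCGACGAGACATATTAGA
CAAAAACACATCAGAACTATTGAATATTCGTCGCTTGTTCGATTCGCAAATTAGATATGCAATCATGAAT
ACAGAACTGTAAGCGAAATGTCGCACGTTACATCAAAATGCAAAAGTAGTGATTAGCGATTGATACGTGA
ACTTGAAGCGTTTTACAGTGTTAGATGTTAGCAGCTGTGTGTCGCATCGATCAGAGAAAA
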