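chrom,l1_start,l1_end,strand,utr5_start,utr5_end,orf1_start,orf1_end,orf2_start,orf2_end,utr3_start,utr3_end
chr1,42,1158,+,1,150,151,448,468,1067,1068,1117
chr1,22886,24005,+,1,150,151,450,471,1070,1071,1120
chr1,12666,13785,-,1,150,151,450,471,1070,1071,1120
chr1,37932,39051,-,1,150,151,450,471,1070,1071,1120
chr1,52312,53430,+,1,150,151,451,472,1071,1072,1119
chr1,42,1158,+,1,150,,448,468,1067,1068,1117
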