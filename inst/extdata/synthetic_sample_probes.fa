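>L1PD_probe_1|orf=1|k=20|offset=87
ACTTATAATTAATCTAATAC
>L1PD_probe_2|orf=1|k=20|offset=168
GCCTTAATCTCGGCAATGTT
>L1PD_probe_3|orf=1|k=20|offset=195
AACTCCTTAAGTGCTTTGAC
>L1PD_probe_4|orf=1|k=20|offset=236
CACAACTGAGTCCTAATGTC
>L1PD_probe_5|orf=1|k=20|offset=257
CAATAGAGAAAGTAATCCTA
>L1PD_probe_6|orf=2|k=20|offset=351
ATCACTACAAGATTTAATTC
>L1PD_probe_7|orf=2|k=20|offset=371
CCAGGACTACACGTAATTAG
>L1PD_probe_8|orf=2|k=20|offset=421
ACAAGAAGTACGGATCCTGT
>L1PD_probe_9|orf=2|k=20|offset=446
TTATTAGTTTGATTTTGTCC
>L1PD_probe_10|orf=2|k=20|offset=486
ATCGTATCTGTTCCACCGTT
>L1PD_probe_11|orf=2|k=20|offset=527
ATTTCGCTCAAGTGACCAGT
>L1PD_probe_12|orf=2|k=20|offset=547
CCTGTAGGGATTTCCTGCGT
>L1PD_probe_13|orf=2|k=20|offset=567
TAGAGATTCTTTGTCCCATT
>L1PD_probe_14|orf=2|k=20|offset=587
GGCCTTCCTAGCTAATAAAT
>L1PD_probe_15|orf=2|k=20|offset=607
ACCCGAAGGCTTTTATAGAC
>L1PD_probe_16|orf=2|k=20|offset=655
ATAATACTGGGCAATAGTAA
>L1PD_probe_17|orf=2|k=20|offset=675
CAAAAATATGGAGCAGCATT
>L1PD_probe_18|orf=2|k=20|offset=705
ATCTCCGTATCAATTCCACT
>L1PD_probe_19|orf=2|k=20|offset=740
ATGTTCTAGGAATATCTATA
>L1PD_probe_20|orf=2|k=20|offset=773
AGCATATTCCCGAATACTTA
>L1PD_probe_21|orf=2|k=20|offset=801
TTGTGGCGGTGACACAAGAT
>L1PD_probe_22|orf=2|k=20|offset=836
CAACGACCAATATACACTTA
>L1PD_probe_23|orf=2|k=20|offset=856
TGACTTAAACAACTCATTAT
>L1PD_probe_24|orf=2|k=20|offset=890
CTTGGAGCCACAAGACGTAA
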