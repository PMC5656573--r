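>fick60
GTCACTTGCCCGAAATTGGACTTCTACTTTGGCGGTAGGCCCTACCGGCGATCAGTATGG
>fick200
TAGTAGAAGGCGCGATGTTATCTACTACAGCGCTGCTCGGAATGGCCGTGAGTTCCCGACATCCAGTACATTCAATCGTCTGGGTTGGCTATGTGGCGGTAATTCGCTCTCGGCAGGCACCGGTCAAGGGTGAGGGACATGCAGCCTGCGCTCATCCCCACCCACACGCCGCTATCCATCGGAGCCATTGTCCAGTTGGA
>fick300N
CACGATTCATTTTCTATAGCAAGACAACCACCTTCTTTTNCGTATCGTCAAGGGGGTNCTGANTNCGTTTGCAAGTATATTGAATTGATCAAGTGTCTCACTTGCCCCCGACCGAATAGCCTNGTCAAGGNACGTTTCTTCACAGTACCCTAATTGCTCGGCAGTNAAGANAGACGGAGGAAGTCTAGCCTTAAGACANACTTCATGTGTANCGAAAGAAGTTCAATCTCCCCAGACCGTGCTTGACGCTCTGGAGTATTCATCTGTATCAGGGTGTCGNCTACTTCATGCACGTATATT
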