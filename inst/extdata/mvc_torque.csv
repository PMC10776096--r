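participant,no_alignment_nm,manual_alignment_nm,automatic_alignment_nm
1,91.33,109.63,113.37
2,124.60,124.57,154.37
3,160.30,171.73,189.30
4,86.04,85.67,99.23
5,147.47,153.27,133.40
6,180.30,203.50,196.43
7,98.38,95.43,91.43
8,159.40,136.47,135.67
9,66.60,67.52,67.61
10,120.67,122.20,118.17
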