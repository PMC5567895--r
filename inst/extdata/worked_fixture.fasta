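>sp1_ind1|Alpha_one
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGTACACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>sp1_ind2|Alpha_one
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGTACACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGCGTACGTACGTACGTACGT
>sp1_ind3|Alpha_one
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGTACACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTATGTACGTACGTACGTACGT
>sp2_ind1|Alpha_two
GTACGTGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>sp2_ind2|Alpha_two
GTACGTGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGCGTACGTACGTACGT
>sp2_ind3|Alpha_two
GTACGTGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTATGTACGTACGTACGT
>sp3_ind1|Beta_three
ACGTACGTACACGTTATAGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>sp3_ind2|Beta_three
ACGTACGTACACGTTATAGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGCGTACGTACGT
>sp3_ind3|Beta_three
ACGTACGTACACGTTATAGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTATGTACGTACGT
>sp4_ind1|Beta_four
ACGTACGTACGTACGTACGTGTACGTTACACGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>sp4_ind2|Beta_four
ACGTACGTACGTACGTACGTGTACGTTACACGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTGCGTACGT
>sp4_ind3|Beta_four
ACGTACGTACGTACGTACGTGTACGTTACACGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTATGTACGT
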