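>P1 synthetic plastid precursor
MASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTG
HASTGHASTGHASTGHASTGHASTGHASTGHASTGHASTGH
>P2 synthetic mitochondrial precursor
MLKVRELKVRELKVRELKVRELKVRELKVRELKVRELKVRELKVRELKVRELKVRELKVR
ELKVRELKVRELKVRELKVRE
>P3 synthetic secreted protein
MQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWNDCQWND
CQWNDCQWNDC
>P4 synthetic cytosolic protein
MFYPITFYPITFYPITFYPITFYPITFYPITFYPITFYPITFYPITFYPITFYPITFYPI
T
>P5 synthetic plastid-encoded protein
MGGSAVGGSAVGGSAVGGSAVGGSAVGGSAVGGSAVGGSAVGGSAVGGSAV
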