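>TRPA1_HUMAN_SYNTHETIC synthetic stand-in, immunogen region = residues 1-100
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQYWNWGNL
>TRPA1_MOUSE_SYNTHETIC synthetic stand-in orthologue
KACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISTFALEITRHEFEYIKDKEFPFYCIEALMKIDDVAFEAIDTVAACYDAGLIFATHEPMKNFKLESFQFCVTVFQIIEEHLIAWSTHRMSIGAPEFKSMLLADFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKMWELTN
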