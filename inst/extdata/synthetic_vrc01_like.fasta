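>germline
GGKWSREASSLPTVPFQDMMYEQCQVKIIYWLSLYDDKWDDTQSRGTMDMHPEETEGGGF
PFCMIQWGDRGAFRGSGHCQKIEAHGQVLIKDLKACFM
>bnab
EGKWSYIALSRPTVMYIVGMDEQCQCKLIYWLSTYDTKWDDTQSRGYADMWAEEVQGGLE
VGCMIAGGCRGSSRGSKHQQWICWHGPVDIKDPVACMC
>bcr_1
GGKWSREASSLPTVPFQDMMYEQCQVKIIYWLSLYDDKWDDTQSRGTMSMHPEETEGGRF
PFCMIQWGDRGAFRKSGACQHIEAAGQVLIKDLKACFM
>bcr_2
GGKWSRESSSLPTVPFQDMMYEQCQVKIIYWLSLYDDKWDDTQSRGTMDMHPEENEGGGW
PFCDSQWRDCGAFRGSGHCQKREAHGQVLIKDLKATFM
>bcr_3
GGKWSREASSLPTVPFQDMMYEQCQVKIIYWLSLYDDKWDDTQSQGTMDMHPEETEGGGF
PFCMIQWGDRGAFRGSGHCQKIHAHGQVLIKDLKACFM
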