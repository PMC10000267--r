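>sp|P00709|LALBA_HUMAN Alpha-lactalbumin precursor (142 aa: 19-residue signal peptide + mature chain)
MRFFVPLFLVGILFPAILAKQFTKCELSQLLKDIDGYGGIALPELICTMFHTSGYDTQAI
VENNESTEYGLFQISNKLWCKSSQVPQSRNICDISCDKFLDDDITDDIMCAKKILDIKGI
DYWLAHKALCTEKLEQWLCEKL
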