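>SYN_PCS_REF1 synthetic PCS-like reference scaffold (constructed, not a natural protein)
FGQNSSSKLGRRMFSYPPLIPVDPTQQPDIVKKADPNDKHSKNVNRNDTAAEPPFCIGDV
EWFVFLGPKRFEKARYLLLSIVAKYRVALMSQISLGSKEDTCMDNCDEYLDCCEYDMKDP
SRNTTDSFVAQPTSNKTSWYQKYIISLARFQLLPRANAQGGHKVSEILFPPTWAWYLCMD
EAKSRDAYRKQNVLIHLYWYRKGCNLMLIWNKWEMFMCGPVTIGPMWARDYVKGDVADNG
QHYLYFCFHDERDKFVGVPPTKATASNWHKKFNLDCNSRMKFKCHVKKRIANCWMSGCLK
VQMHWWAIWWCIFIIDDKGHKNDKYYDPLQMGYGYPLDLSMSDHFARAISQTKWGAASDK
WNQCDGMPGSCCEMHTCNHQQLDWHCGVGNFHHVSLSNMPRLLKGRAAYPPVQQPRAIVG
YDRMRVMFCWQSWKIVARKTIGMVYYCKRPKEWMWPSCLPPNDYEYTKMPGKDGENARDY
HARMQ
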