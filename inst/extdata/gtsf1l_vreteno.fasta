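>BmGtsf1L
MDDPFVSCPYNPIHRVPRSRLQRHIVKCEWINPTMIACPYNATHRYTQEDMKFHVLNCPS
KTSIFPIEKPPKTVASITTPKIILQKEYLPETDPNHEIWDD
>BmVreteno
MSNHSRPQRRREWDPMRDDFNEHTYDVQYADDNAGEQVQLDHTKLYIINIPRGLSEDGIR
AAFSKHGKVLSARLSKNPNKRFAIVQFETASEAKLAMMKMNGSEPLNLKISIAHKTIRKT
QHDNKDRNYSTSRNGHCSRDEASSISSKGWNMRNLDDVMNNDEIDEIDDMIHEDHDDNLD
LELDMLTLKQLKIKEEQLMCKRRLLLRHAEKRQVAPHSSAGRSVLPDGRIVVRNNANETD
SAEVEPSFAGAGSESLKTPGLERNASRQCVKCGAPADWYCSRCAITPYCSQTCQTRDWTE
RHKSVCHYLAPLKTAGGFEAEATSSKSVSNSTPMRSSHSPPTKQQRGEADETDNKAKNIQ
EPRQNYHRPSNSGPNKNIPGKNQDPRRPATSREAIEEETEERGARNPKPAEATKDKHHPM
NPVTFQRRQLKSNPVVDAQPAPREQQQPAATRAPEASPTEQRESTRRTLVPDRCLIDSLS
EGDVVLVSVELKASECCTKQGGYVCLSMHEKYESDYQKLCEDYVLDCEADSDEYKIITGD
TFSYLSPEDGGWYRARALNTTMAALLDGSKVVYLRMNDKVKKLPAKYSGIPEFCCVLNAD
VEVGLNLKCSLLSKTPNGFKVTLENVETEANVGEGEITRWIPEVDYPPPVKNVPVQRSVE
IPEVPRPEIKNKSRVILVDATDVQRVFVRPADTRSQKAFDNILQDVLLYGTTAEPLKEPP
SKGQTVVSKYTDNLHYRALCKRTSVNKNKYLLEYIEYGNIEITQLNRLYPCPEHLSVTSL
ASLTSHVQLDTTVGELTPRALEYIETIKEEEMILTLSSGGDTAQSGAALVNLTLVKNNDN
VNKRIEELCTPEWKKLELKGVDVIETERLMYGTALDYIELPAAPFDLQVLDEVGLDSGNI
SGCPTNSDYVRYVMTKLPARMREYCESEFGRQPYLPAAEELCIAQLPPSSEWHRAVVLEQ
ILGPGGGTARVLFVDHGNVAEVPVSSLRKMLAEFVTDLPAVACQIVIEDFPKQATAEMLA
KARRFMSGPDKARAAQLPVRGCDKQDVGIYAIRVPELLEAMTE
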