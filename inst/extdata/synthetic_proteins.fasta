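>SYN01 synthetic invented protein 1
ILGFVSTRSIFNCNVVKLFLHLKWMTDAFQQLLISSKVGGPMYEDLRKLMMFTELEVSVL
AAVKVTLYIDGTMTLPPFYLTGGFNFEHKQNQVEKEHAISGVHLADSSTMLLVDSEGPAI
WELGAKAVYDFGSTVVDQSENKFRNYAEGYKSDIVSELYTRRGDKML
>SYN02 synthetic invented protein 2
PKETHFAQLYLVASVPLLGYHAGMKFAAAMHEIESGGELYMKDLAVQDQINDVLVPPISG
GLISKGNLALGHRKKPVESAKTAFDPLLSQQRPTRMSLGSRFFMEQWHIWQGDLGIGYKL
AASKRDVPDVSLCFAQPAAMLVQFLYKSSLRINEENLSSLRRSPANVVEMEPALLYKNFA
LRENHLILTF
>SYN03 synthetic invented protein 3
MQGKQCHGVCKPLLPAKPFPSLDGFDNLGGDERHGDLLWSHFSVVVSEIRNQVQMGHTGR
PMEESSKDTCSVEGTMMNYTGPIDSACRQIARSLLRDRIQEKQIFMLGHNEIYAPVDHWN
HTVSLPDERETVFGWEANYQNNLESPSQPLLAHTLDLCSETSNGGLE
>SYN04 synthetic invented protein 4
LRMLIGVERAVVTSRNQIRASALTNGELAHILGHIMNNLDEDIKFAGKDSYIKPGPPFSA
LYRGEAASRSEAKNAALRSEAKPTDCVGGPIQDLAVVNSPQVLLPKGIRSSDTPIAVSFV
KLQAREIELIYVMWWDDLLSLASVEPIGARNDIND
>SYN05 synthetic invented protein 5
KDRKSGTTDHKKLLIHWVKLVYVINYELHPVVTDGEIDNGRDSVYSGSSGLVAVTGWLGL
GEARDEYLCVPTNHSNKAMASPTVQNIKNAELTKPSALPWAGVEIPNTFLPTVAVNQGLS
PLWNVQADGAYVAPETLPEETSSSVERRHYDSALESFETLGEARLAACWEVARPFGKYLP
LTSARGYRSPSQGISTGTITYENRLNHK
>SYN06 synthetic invented protein 6
SHSRLLWICELGKLAFFPEDMEFSLKIIGLFSTYAFFGWRLYFVWFYKATNGILVDRGFS
YAIIVESKIWVSKLYYERESSLTFLSGHAFGIDGQFMPLFPSLDKNQIAAVGPSHRTIFE
AGVFPMQLFKSEVFVLAVNKRLPIVAIAGLLKEHYLIRIKWKEHEPANFTVGGLGPLTVV
IVEVESSFYADIEYIKELQANTIIVTEENKTLKVKRAI
>SYN07 synthetic invented protein 7
DSAKAESSAMAATAVIEKIVRNVNRTVANSLLVIRILYFNDALVVPADQISGNVRKGFYE
KTGAALRRGLEAIEIGSLAIDLQAGCRRRAMPRVKSTTLFREGSKNITVETFFSQIIKLV
NEERIETIFVPDNEVKCVRKVSSTRMMDGKHKEQWPHVAQKSVITLETISLSHDQRDWWI
KMRTELQTCLQNIVVIDFDICAHYLVHENDTKPAICTVWN
>SYN08 synthetic invented protein 8
RIVPHCALSGGTKMLDHQRQWMVEQALETNQSVAPFEAAESGAVEKKPSQFVPVRDQQKL
LLVNIPVISIVCRAAQSVLIVELLNQNFTEPRGVDNHAITTQGFRIASIGQKCGGMLFFG
DIDAPDEEAKPLSPLPKNHLGLSPIECPFRAAQILCQKRIFPKFVGLNRAGL
>SYN09 synthetic invented protein 9
YRSRDKRRLQHSFVSNVCPLTTAKEMTPGEFLELGLKIKHTHRAEVAYLVMPPKCQLKGP
HTLEAAFVPLGRFGHGDHPIVRLFVEGKYLLRGQNGKRRPSQNVREDPNSEHGEHSPVAV
NFNPSRSCISIINDVETSSEQRVEADRKRKVLVCDGSDGFD
>SYN10 synthetic invented protein 10
MNLKLDLKYKIEFTEWKILREAEVQSAVGEPYKLFVNAQDFIEIVKKVIQGITMCVACIL
RHSGGKSQVDSVPAQSVQQAIECQEENSRADGFAPTAILKLANALPMDFRSFWALKVESG
HDNGPKVVTDGRVEISHANVNDGIGIDIHLSEVTA
>SYN11 synthetic invented protein 11
ECKLSRERVMLVCVTAPALRQTLTLVSTSMWLKALRPTFEANKGFGSVMAIKYRHRRIHF
YMVDGKDGHISQTGESLKQQIEMDAEKKAIEDKSGDLLGRVDPSAGIDSSTDGVMRRGLL
TDYTLFVGLKPVKGSLIILSNAMLELLGSGHTDSRVRNLAVCQDFLNYQHLNLNTYFTPT
LEVAEEYTLRCKKTGRAQMTEAK
>SYN12 synthetic invented protein 12
KKSDTRLIADTWFEINLIGGIIPGQALTRKPSAAAKCSLTADGRPSEEFLVKIELPLDDV
GLSITVIKSFNEDAAPASLNGQINLDAATPFCSSLAHTGQLWILSGREYIHISVYLGRQK
VETLDPLFISHLVMELAGNKLSCLNTKVPYEVMCLQLKEADQFLRHDMDSIPFKLGLKKP
QFDVVGYSLLENSWGFQSKILMSFNMVAHT
>SYN13 synthetic invented protein 13
IKEHLKEVGAATRSIILSLVNGQVVQHRELIAMDTVVTMELAEKGNGTFLEGVVVHNPPF
GDETQDYVAVEAKLLVFIRVQGALERPPPLWININKAIHCDTEYYQVHSVAVSGLVYYEL
FQTLHDQEAQVILYQQSSREIIAFHKLDRIEIPADGQEQLECLIEINLYISYNLTIALQW
ERSESIHGLACTRDSIRLRVVRISICLLSE
>SYN14 synthetic invented protein 14
AREIISRATITDKRWHMESALVRDATELNSGFSRMAVMGVPAIFVKFLAPGLYQFVCSHE
IDKADAKFYVTLLDLFCAFFFMTDATMGHTTAGVLRSSSDHAERDHVARTDVRHLSGAYG
ASEKGKAFVIQGPTLPESARLSKLLQLLRQFEEGLGDVRPASNWPQMEKKPIHMSLPGKH
PIDRIGVKGNNIK
>SYN15 synthetic invented protein 15
DTIINEVLGAGKPCTLNFRWRRDLRIFTLIPTTPGVICLELVSDLQEKGTADKVSGVEET
YLMASILLEDDLSAQAQEVVPLVVSKDVILVEAILYKAVQGPQGRVARTRHQIGGGRGKW
VHYDPTSICWLEGGSMSEATVVILVAEYIVWIKVTLIGNNAPLMSVDFF
>SYN16 synthetic invented protein 16
RSSKARPPNAPPGIEASELLEERESMLYHHVSDNMLYSRRLDTVSRYPSAAGTRNNEDTS
QSAALEIASDVAYNGNIGEQNMSPGIVAGNFYRGFVFHKTRQPVSPPARLLEELVEYYCD
MDFAQSTGPMRMIVQLVITLNDLIFFIHLFQLSCMVNLKCLCLTVEGVLHKLLGDQTRAI
GNIKDLRDNWDKYSERILN
>SYN17 synthetic invented protein 17
NPLRDGFLRDNPRDLRKIVQVEERIQFLNAKTIFGLRVFQIALAILDLVLGAGTAWGTTQ
IKRELVYHRRLKYEGAGQPISSPQGDGELKILRASYARPSLGRKHSGELKDPHEVVFAVQ
SGQILNLVKLSFLEAFIGAPGVDGALYPTNTVPGPATTLGSSPPVQVKNLAGEVAVPFQI
LFVEHIGAKRATEKALT
>SYN18 synthetic invented protein 18
TSILGTLDPGLVATSLAAVSVAPKVEHEDAGELSETKSNGGEVCETKARLMSFPLDRRDS
LIFAVELNLVLEDSQADFEGHYEVYEADLSTQRKYIAEVKNFNEPFKVMRLDIEISGASV
ASSNGCMLPPKRFPELDSLVTKPKHMQGVLDDMTTLESWQARTKSCKLKEKKWQGKRNIR
LVVNLDGRVNQFGVPAKTLFQRKGEAIVGPPIL
>SYN19 synthetic invented protein 19
AFSLKGQKVVKIKSKVFDIRIERHWTPRAFILLLEMRKFWRTLLALDITMKRRPRYPIHK
FRQVADSCIIMNFQGPLDVGVRDTDDTLTQCLDSSGDMPTRRAPTNAGTKPLVIKEDNDA
IQKFHILKVHGSISLTSRLDDPVNLHGGRDGSTSHLMKSLIE
>SYN20 synthetic invented protein 20
VVDHPENAEDFHHFAISMSTGHILVSRRPVIGLPKSVNLGYRLDEVRAFVESSVDQAIVS
SGKEVSPRLYAAILFERAVRALPELPNCGTIVLLTGKESIRFMLVENKLANLDDNESIFS
KMKAVRGPRHPRGTEDPLFIYGLILAGNRISPPTVPPDQIDAIGEGYTEKRFVHRVRERE
LNLRDSVTITYISSGAQFDISEAPS
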