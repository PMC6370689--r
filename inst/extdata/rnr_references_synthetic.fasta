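>NrdB_Ia_syn synthetic stand-in
VQAYCLLDVMSQFTNDHKQGNSAKWQGSEFNDWHPGFVYSPEYGDPGWNAMAWIYRFGHLIWVIGNYIYRYSITPYQYCVYFHIDGINNHRWCGQQMGNCRAAWHMCGMINKHTSECSHGQYYRGLVWVNHWKDFFVMEPIDMLKHDMMAYVLVGQCYVHEPMYSSWQGVINPIDFSQQALEDWAMCIILVYDQPCTQEMRYHFEAWDWHAFGLGHMFQCRGIEGIRMAPVWMNEKLDEEYHSYEVAVQTSENKGMMSRGNCSEWHIPRSVEDWFFSMKVYCRKTGCRERTRVYPTVQNVGCYQDRWHCETGGNSSWHIQTVDSAESPSYLYEYQMQKFRAHQFFDNWAWIHIGSYQGYTQLCHRSEYKSMLKAP
>NrdB_Ib_syn synthetic stand-in
TIPRDHMTITWYVEPGQFMVLNGWDTNHLPRLAHKKAETQYDLGMEMECNHAESSGPTEHDYKHWIDDFYHSPLYGELTYQHSMLGKDNSPCFCTYMEPAHCKIYTRRYHWWSHACEAWIKAGKEDSFCAISSDWIDSRCDEMMGSKIQWCNNTCIPEVYWLNFEVDMCHYGPWQLYARCLNYTVWSQPRDEYSHPVDDGEIWVAVRKLGTPVGHRMIIPYNYTQNDQNQHLMNYLSIGHRDGWFGQRHVYYSGVDNASCAHSYEFTRMVNQMPVGNDDQKGHFFKYPILNQWPPMHGKCRWETGESGLHWMMQCQYDAQQGSRVKMTVA
>NrdB_Ic_syn synthetic stand-in
WWRIMTTVFYKREQIQMGRLMYHLLADWLDQCDKMRPDRWYNCMIFSKSGFPMPGWPIFFFTVFFTVIDWKYLAGAVTSFPICKHETHELQYNQMDSNASQTLVYEKVAMKCQLITGPEETMHIYEFSAPAHFQCNDCKLVSWAHWHWILWIVVRTKDVAGSYCPCQTYCIPMENHFWTYFSDQKRMDTKNSEHVQTISQLWDMKINQEQLWDSICSNWIHQNIWDESDHNYCSAADFVHHTIALLQFEGEMQHRVFNFMPKKKGPVRKPPIVGEDDMMHRNQIVAWLVVYMILPTMGNQFVWWHNWHSIGPEDIICAAVEADFKHGLHCYHYDYHCRKTMLHMYE
>NrdB_Id_syn synthetic stand-in
CDRCDRNHNYADLWNSYLREDNMWDPAPGVPLNASHARHSCCPEMYKHLCWLICKNFSVYMVLKAGEVAWWCCNDSAHQPQPNYTHRMCSVRARICEFPHIPMYTGNLTNAHMWYSYWHDSWSTITEKCCFQPWEYKMIDVMFVCDHGANVIRSQWNLKEQTEFYCQLDMWMWAGQHLAGAKWMDTLLFCCIKDEAYHAYKIIDDGDANVFSAAFCMPHRKTQIHVLGKKVDSTHELVFWNRHNAFCSVHCNFNQEVCNCYGKWRLKLTNSRTEMLKDDYENGMRGRWGHGSDQEGSNKIHLLWGHKNFTQYECLFGKRIGCMSHGRKHQYIVLFASMHT
>NrdB_Ie_syn synthetic stand-in
KAHQFEWIYVVRCIYKLGASLSQAKLQWWNHPCVFFYSNESSRSMWVVFYGMVCQFYWAAEEISYKESYECVKIWMTYLQPRCGDAESQGPVRHFFENVQALKLARPEHYQLIFMVHRHRMGYCCDCRLQTWIALQHLMVLSFMKPKQDAPSPWKSGTPVQSLCPGDGFHSLQPHPVGYYGKERKMCQCHKFEHFPDNHMLYKMIHAVDKDVHNHLGKNCGQRIDPVQWKDDFSWFFQRPPRPSQNLLFIFWQQILWQASGHNMMMYAEIRNLTSNGAIASIQVIMMILCTFTEKDFCPSSESEMFQHNPNFDWAMVCFPAVGMDPQRYWCFKCKCDRWFTAPYGVETSS
>NrdA_Ia_syn synthetic stand-in
TPQWINWAIGYPMPSYKPQEPQFTPVCTCGIIQMPILHQPQFYAFWIQAAMSFKNSKPNHVALIKYACWRSYALHHTVHRDVLGPKGVCRHAKHAVDVMHQFCWKSNGCPFCGPSAYGCKFFYMPTYTHANHYELCMDGECTQNPKPLCMYSYFKMFVVPYRCIWYNQLTKWNMWKVVEGADWCHCYLMTYLCPVVYKYITWDLFKNLIVCTEGRAFPVSSADLCLCQHCANPYEVNAWPDPLTQEIWQCLDNWETERLKQSGIVTMAVKMYWLWYVYQEKPVAANQVTPDQSIEDYSQGFPWSNHNPQDTMCFECPQEPEHMWTANQECSTRVAFAEYPYMSYQIAEVAGRLALMIFCFFEWKRHDHYVSQMRMFCCDGSRWQWEGENQNGFNKMRVTLVINLKNESATYCMNYYGDKKYYHRYQQSGTGMMNWQNGCIERNTMEMEHWIRIMGYTLSEQCQIAPFWLMKVYMHGWRLAGGKEFCLCRYVQQMAQEMMENPYQEGAELTRLNNHPPQSPPRQTQTSTGKHLKFPDIQQWSKTQIGAECWMLVKDEMGSHTFDWDKKPICLNKNPPNHQQKYVGHLVGNDPEICTYFCNNSSMRYFVRTNFFVDCYGDYTRFCWSRPNRDAIAQQRNVFGIMGPQHTDHKMLNAVHPASIAQIWCERNSALMSEVLDFWESPACDLHCMWRVDQQMMQDTGFIVERNIPENFEKMQMGWHTACRLKWRQYYPSQGIDWGWNRPNTVCCDRMVWCFDDWFSV
>NrdA_Ib_syn synthetic stand-in
WATGFAYHVNDYCSYHPCDWMMANGGTWDYDEWKSEWGHCWKYWTCEPAFDQMINHTRAYIYTIGDEQFGQSFFPYISWLPWKQNKRWVKNILGMQAVDMKCIFGVNVNRDMKVGLRWWVSANLLCWACGCWESGTKYRYVVDVKFDANNPVDHTDIIWWDWQFSIRVPSKQDMRCVHYAEIMACLRLIMHFYYEMYKRWHREKEVGWMCWHHCKWGMQCNDYGCQSWAGHCFWPSWRERCIEYKVILPHRFEICPFLCCKFPFKNKQPVHNEEFVFMRGTTSMDQIHMQLDPYYEKHHQKKMCDYTYWPDMQHNRCFYYNTKHFYGKYILDWQHQHPIHGAHSTTASMDIGVPALPEAADRHRDTACMIKADSYGAQNYICYVWSMVWCREPPVPCSCCDIPDIDNKMPRCQTKFRDGTKVDSWFQCGLIRRGNTNVCGERMTTPNMMPVQKFACLTSCGCTCAHAAQNKGIITPRGDALEPFSEELKQLMEQHFEICTHNRQWTASSLLAEEQNYRQKWPMEDLFNALSYCSAHYMVADEYQIVWYYPNMTHAWEAWIWSVASNRRHCIDRFQCLVIVGIKNQQTHCKIDLPEGISDIAYNLWSIPEGKTVWGIMPKWCPFISKRSKVLCINFNVGSEIPDERDTNEGKQHWPREYCCPECWMQWMQPETIQGIDFHGLTSANFGNREETYNKTNGMIAFPTPMHQGKSFNKTGSGRTISTHLKFAAYYNGLLKSEPDDYIKEIVSSYWSNKVNNMWKP
>NrdA_Ic_syn synthetic stand-in
ESSNPRTGFAAFQYTKVVQVTTQCQFTMSGVFAWTTVLVCNWEANPQPVMICYCGLFTVSCIESFHWMCVRENFNPVIYEKIYGRCNPPDIDWQFTIYGRAVFFYKEMHEHSSFDRLYSGWMHKLRDFPWGCDQVHCQITWDHQYAIMCMIYVFCMAHSRAAKKNNENMQLAHKMLMHMADQPVRCHGKHPYAYCLVRTWPICIFRKFQEEADNGFPAEKELFRCFHSISPVHPMQEIIEVLDHRMRQDPWAYKYWIMYRDDGWLTWSKTLNGIGNRHTGWWNTQTPYECFGQKMLAAHKNNCKGKAGMPRGWDGMQMCTHETNGFWVIDQDTKALYEWVQDNTLIHAFFNHMNNQIYHMKGLTDIFYQCFPEMESLYREWFWQRSEIFGQWFWRRQLSKESRFYWMHERTSLEDRAPQPRCNALVNPIDDGVRPDNNCMEKVCQHYFSATICRELLPYGICQGRGQPGWSGWITDDMQHPVIYMAYMKYAEVCTPETIYCWNSEQHLTDVSPYCNLTERVFHFLHRNPPPQSQYHGCGCCFKGPFLSVHRKQSRNWVLAHVRLYHKPITLCSVIATQQWRNIPADFFQHMIFTADANNLWHSKQIAYAQWNAILPIHEPIYTESKEMVFCETACITDVGPSYQYAGGHYSKVWYHHKNNYMTQIDHYIATFYTGYNPYTRDFEFWRPDLGYEIGPTWSRKAYDFVICRERHMFHEMHMRIIFRKREGYYYYTMVAISPQCIWKRGLFQNEQIYGYENDWH
>NrdA_Id_syn synthetic stand-in
HNMWGEVVFLGYRATCWRNFWLKTELIHMCWIHYAKCQYSTICCRIVDKFKCWDEPPWWGRFDMFVKCANLCWALWPCIRHYVDREPCQGYKCGFHMQIDMERCQRRYNRCTNFHPRIMDYGGLYHGKCKKKNECVEWNCMKSNHFDRICDITVTFEHKQQVSDWQSAELKWWIWSNREKYCEFDNGEFEWRGIQSRRIADVMTSDMIKSTWWMYLMFNGFEIGCKQGDMKHFEDENMNTQSKREESGCTDSREKQNGHWVKTVTFVDMQLDGNPGSVGNNNRQFPCEIEQHISHIIVYHPCWQPYRQHYADIDNNWWCWWCLTLAIKSGIFGQHRCLEPDCHDISCDHVVALKICYMGIWNLQYYCGFSPHQDMEDHDEVMIDRWNQIGVDPMTDSYHSIHTNESHIKREKEMRVFLMMIITYEQMLFPLFQQMMNFCCELVAVQGSTIETASEFESSYHCSCINTNHCIAMRIKVGGAFWYRMQDLKWELNIGTIPDQQISDAPQCTMFWWNMLDCWKNCPQVFNFLTMLHPPIMVTYWKNNFPAYARDHLHMMECNIPRNLAACWLRGVKKFLRTLVEMQIKDISKTTQIWTQYHGPEIHRPEMVMAATDWELFQCRMFKYSYHAIRPSIESMKQSRADGGTVCTEYGSTSQECKNVGHYKGDLHHVEKPAGCNFNTKKQVDWGVSTTSVEVLVTKQLAIYPKTWDEVEFWPEQHSMESCDWPGKFYYMRADVYPHNGKGPGHMNGHAMGNRDWATER
>NrdA_Ie_syn synthetic stand-in
PFEAWACSQDTIRCIYVLAWCVGQFMNCQAASTSPVNHSMDEQAQENLADIHRVYCTMVNCSTMEMLKYVDVFGGQLAQAMLWHRDDCILKDDKEWCAFHRYANYAKVITTNCWYVWQEIWKKPFRMCTFDYLVIHVDGQTKCIMWYIVYTGCKKRGFAKLGSDEQFFWVCNFYKKRIVGRMYGVTIHDTFFTDTLMGHFFTKPHYNLWPQVYFCVRKAAETIFCTRPIYCKPNHTKWYVIQGVCTTQQGKTEPMFHAPFPDTLRHNCDVDDTNKKVNWMSQCEWIQGTGTCGYSTAPAWSCNAEHIDHKWGMRTLFIGRPVHRTMQLSSLYGLMVYTSKDSEGKTWEAYPMYYQPFFSRPHWKLCQPMNFAINPSRIIDYDEQNIEYIWCIPFEIRDCPMDRPFSFRASIWPQTLRSSQFKEPYLWCTGSYCKVVNTCKENKNTMSTDKEMWCGMNWHMYCGMMAAVGDFARKKNVHFMAVDKAQRWTFGMRGPAYNVKEENLKVYACWADPWYPECNMFTTKCSQTQDKEADNAGIINTPNFWCYTIQMANMSGFIYWSFVQADNDEVAGGEMSADYQDMFNPHKFSQAFSYAKCLWKEWMPSLWYAVLDGAKDMPVTTMMKSGDFIYEIMVDQAAVTAKNCYHHFYGVREKFFGQFRCDKEGVLLWYMHNVWCALISIRACALIFDKCKNYKDSTCCELRDSFCGEWWNYLNYYAAIQEQSKYNKCYYDFMSNLIAGISLMLNESPVNGYTYIFPSYM
>NrdJ_II_syn synthetic stand-in
TILSPQWMPLCQMMMPRQTQEYKFLACWSILLFEYIIWVLHNTTKTFIENVKIFMQANSCNYIMVVELKHCASTVWIMQTRAKPYRAWHDWGNEGHTKSHCKDHFIEIMVWIQCGRMGGIDKECDWSWTFYMQPRPYLNPSVDDAERIFEYECDICQQWVNYYLYPMWYTVNSFKTPVWPAHAANWQKAPYGNESYSFHDMFRECCTHPSGGWPMIRTVGLRHRHQLIIMHTICCAWDFNSQMEAYVDDSRSEPPWPWKDSFCGLGCIPPNRIRAWVIIFTSDNDNMSKMEPHCIFMGIDQDYKLGMRHHLGPFEKTSAKRDWEANNQDNERRHEMDMEQPVPVRPTMMRKKNIHGAAIQASTYIREFTEKKLHGDIAEEGLWMTMTLQILHRSKCRQSHQFKTFNACMEHSCDRHDLTERECVNLLAWCEKNLGANSNFLPMLHYLTMQNFYYEWEKNVQCAGNQVDNCNTERFICTLGIPWQHEEERVQNIPFEGDFHGDQHKMRGYDSYHYSKHCVRHWMNQAPLSPEMYHWEPWIWNVATSMLNWVSRTPFHRAVVPWFCVRMDLGWIQPLKKEICEWNHFRKYVQKDCYALHPQRCHQTEVETGYIESTDDNGTEIKCLWFLNKCRSYFHHRKLSFQIHKGMIPLPCAHQKKTEQLACGVLLIYTNFAWTEKRCQTILMTHYRQPHDQMATNHES
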