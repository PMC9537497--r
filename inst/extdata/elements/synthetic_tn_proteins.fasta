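>tn4656_tnpA
MVHTRECITSKLLISMLCSPMECTTPTFATNKEWMNGTEWPHSPEMCSEMRGSNPYMMVHFSEKGFGTMDWTAADWTHYNPGKPPENNNVSCTVFTMSCNYCPLMFMFKAKINLYTCVTWPAIYGDELCNWWNATPRLSPGGDNLVAIVAEAYTSTMPAMIGYWYPIPLIDEADMFCSQAAIWERRPFIQHHMWENKYHTPAGPEKERDDISHEDWNSMRTEPCKERQSNHRVWRNTQSV
>tn4656_tnpR
MVKDTKGCTQMSDMCYDCVWYASIMSTYKRLCWYQPLWTHHTMHLNNFMCMLVHLIDDRTLFHITGHMLLACSKSAWKPNYMVWQYCHNRLSVKLQADFAKIMLQLQRQVFQLILGGENE
>tn4656_mcpT
MAESPEHSSSMWFLAEMRDAMHEAFKLLIANAQKTIKTRYKNMKTFHVWLKWRIRVIFWVCEACLNWGHVWIGYVDWNPVGWANFCSVHHSENFMCYYPLSWQLRDGIHDPNCDKCWNQCYNMKAQICHYKMRSARSGIPVINIVMGGFI
>tn4656_istB
MQRRDDNIYMNCWGGDKIPSRGQALRFVPINHHEHMCRRNRYATPGCDSCEDYIKKYFPDKWHKMNLQMTDHWTHRGINFPLQLMLEFQHNYAISNPETL
>tn5053_tnpA
MESSKHGSCNHACCKVYMPCASYVQFLYPDIHTAWMCKFHLVFTHKRGQYESNFMVCFECMCMRTKNNWVKIKSEVVWACAHMHLGKEFYAACYFDCWCESPLYLVMYSYCKDVLGGFHNCQCDMQHMSEVDHGCIGMWTRGNFKNMYKYDGSETPTGSGEWQIKHVCLCEDRQHSMYGQRCLWTTNLSMFRKPLSCNHQSASQKDQYAGGYSMEYLPYMVKCYGNYHGW
>tn5053_tnpR
MDTIPGTAGNKTIHRLGTERCVLCQNSFLNQSLTEIDIEKKPPIGGYVAYVGFEWEMVILRWRLEECRMDRNDWGITNALHTCPSARKNCKNQGAFNFCWLNKETFLFGI
>tn5053_merR
MHDPHCWMKTALADCMDLGTWYPDVAQRDAVARHSFLQCNPYVYTVDWQLDFVGSTQQSEKAPKKDYLALKHPWGRCWWIMGGHNFTCKQQNFIRRHAHQFQRNFESVDKLASYLICRSQGMTWHYDIRG
>tn5053_merT
MFECICNHTTWCHKWMTGVHPHGPMYHCTCYKDMWSKMHKAVYWEMHQCDPPEMALQEKYAVYLDNMSHTWCNHIILITGHMSFTINAWT
>tn5053_merA
MMIWHKSMMRWKDKQFWRNAYDMSRAIREMCPSWMVDYCPHPSNCDVAHINMGIAVDNAWCFIDHVYIEEMHNNIQINIMMLGDHDMRPLDDTKCKVKWNKEPLNHKKWRYMPLVCMPLVHHMFNYIENSTKTIPDPYMALLKVEMNLAGMWSPHYKMNQESAENKEMFFEESDLYFALV
>tn5563_tnpA
MICIGSLRQMKGIPGMPLDRHCFQNIPLGWGRVACFMRSRMRPMPFWPVRFYFWMQQSTFRVITWCCLSEYRKATMSGRMPWHNSRNWVKASGASNIIFDQPHPLPNNIALWTRQEAEVKSSHRWQNTFDTAVFDFGQTLCCLAHQNHPIDMEQLRARNMDYRVMNPLILTTCVMNVRYMQNWFDQIDQIYDREAAWAIQPKDPTLFVELVWKFDMTEQPAIHSEEDDCRKQERIGWSGLIWDVRNVSYI
>tn5563_tnpR
MAMFNQRCFRIQWEYQYHESNIYHIKSKKVDENGLCFPTPGRFHAQEWIHLRHGKHSREQFVQEGDRDWPCDNKMVCKYMDEDSDMCVWSASAYMAVIAT
>tn5563_merP
MRVYDFQHDAKHTHKKKGTIFPFTGRADNRHLKKTGPYWKKTWMVYIMPHMTFNHDFLGMDIKCKGEIKRPMPSISEYPQ
>tn5563_pilT
MMCHWTPQFAYWQSTAIREMRNSDAWNRKNRWANIVMHIRCLLMNIKRWHTRIPQRLRPLSCMWFCRHVQIDWFSYRGCICTCQTRVAEWCQEMGKEIRDQRMYASSRREATPYTANQESWCTPLCQSMAEKCPGWIMDY
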