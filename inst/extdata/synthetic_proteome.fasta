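>Rpb1 synthetic toy protein
LNYIDTEEDIWKLIYGHHNGDRVVWPDSPVFIKYNETQLSANWRHYEIHYSKTFFSHGIQ
NSRYWVMNSYDMQIKFQQWYARENPDGVNWKEVWQLRSAFMNLFDMGL
>Rpb2 synthetic toy protein
FQMHEWWKWGDSVSTYIRHTYEYEKMEYESNMHSRWGSISYWWQIKTQHFNRHYDEHIAD
KYPNTDENYYDIRHYAHNYQWNHKFAYLNNVWRQWFFHKFVHDIDVRPIPAGNFIHYKYT
EWMRWQEHSMFHKHFVGTAW
>Rpb3 synthetic toy protein
QLPITMDTTWTKYDIMDDINWVRHHFGGLAPTWEKPTQGDNRLITSHLHKDYPSEVWMYS
TRPPLEWSHVSPKWSYSEYEAAGVRDVESIAKIASGSDNQSRGEVSHPWKWEVVNMRQAA
>Rpb4 synthetic toy protein
DYSHVKWEDHMQPIRDPSAAIKDLQMWQEDMRWPIGDNHSYKDLSTYNEHQMRAMYEFKQ
VQTPEAAYIRTQGNDYQWKYNFFFLGTMMRGLQFQEWKLHTQT
>Rpb5 synthetic toy protein
SVEHYTWNPQKAVHMAARQVVPIQGAEKPTSNQDSSIRQWYVSQKFFNLNMLYEMWRADW
NQQFTIIKGNTGTPPRQDFWHGDKWMAEYMEVQTRSHEWAHFW
>Rpb6 synthetic toy protein
YNPGFFDGKGFIFQRTDHSWFIYIKDQFNEDNYARFEDIYAWMIKMSPHFTSARVVMNDD
GWEKFHSPYRLPSDNHIMNVFKYDVVDSQVYRGQYGMGMWF
>Rpb7 synthetic toy protein
ESMSTDHKVEWDGPRDPTHYAKWAHILYYWEVDRNYGFTQVSKYIFGAGFAVWIRIHNFE
HPKWISNGWEEGRSFFVWGWWDTKYYQYPVYWMRHNYAHSHWLKMGNFHEDITRHISF
>Rpb8 synthetic toy protein
ASFTWDPANKQNIIQHRGVQQVKPWHWMTGGDTRLWGVMGKTHIEPGYRLAYAVVFEKQF
MWPFGRGHNQTEYVKGQSIDRTHYHFASSGKWWGYGEERHYHNSKQMGVWMD
>Rpb9 synthetic toy protein
HHEVGQTGKVIIFWDNIRNSMDVELKVNEIPVQRGMHYFNWAPPGKSNALARHPQQWKQN
SGGFMEWRYMYDWAEKWLSTIVPARYEEFTIKAYQPPMGLQGWRLSDIWFKANVHQGRAL
EVWNKFDVHGLMRFAEP
>Rpb10 synthetic toy protein
LDWSAAIIKSLMLGMWDRPWQHWGEPKAGDYDNERMAVFHSLKIIWNIFHAIRYFITNTH
KTTSTWIMTTRLAQGVGQKYFEQHTGFDYP
>Rpb11 synthetic toy protein
SWNGTSHDSGKYTENSAPEDPRATNDEETNKHQLDYQHNIFYRANMLQNMFFKDFWYHHV
AIHRHEDADSNISNKASHFDHTRMWWPATHNAFTKAPWYPARSSEDI
>Rpb12 synthetic toy protein
APGPMKTDEMETMRFWLHSHQKSIWVWAETRATSHQMKGEQMFAIRPSAGDPNQVYKWYA
IITRVPQFMQDKLNLSDSYRPAHVIMWDNKIGIFQILRLIQGVYVMDKGGFSNFTMYRQF
ESWSKNNMIQGDVWGH
>TBP synthetic toy protein
YQWIFVKTQWNWAHRNGLEAAINIEKTPVHYDHVRPPHPWKFAMSVRLDELLLFEKGWIL
EIIHWMRQMYWWKVTWVDLINVTHRIPDNPYVKEMAGLQRDDPGT
>TOA1 synthetic toy protein
HVPLQKTIDASRSIFWLFEKISAEWQFWRTPQPWKWESYLDDVSDLRWFSDMTDSEQKWF
SYHMVHDRWHQLDKQAFGYQASPERQTPGGQDMIKPHSFVWAN
>TOA2 synthetic toy protein
WNPYMHFTYTKTPQTVPRMDVTNPLVKDYLQQQQTMRGPPGQQTKYGTNWIENRWQVTYK
WIAPLQNAQPHRQNHEIKELFVIEFFRVAFQYLNKWHLMHFRWAFWAW
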