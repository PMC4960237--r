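>Amuc_1098 PilQ type IV pili secretin (SYNTHETIC stand-in sequence; length matches the documented 907-residue protein, residues are simulated)
WVDPELAPITAYAAEVFQEDDNTQLKSYDLHSGIVIHVKYKISSLLTNLYAFVAAQCEPH
AEIADKKGNESAQGAVDVRRELLCAPLENSAAPTSNASNKSRAEVLCALKRTGFLNRYDR
EQELAPRWHAADFLAQSKVLRRILADLPSNEDYGEKVVWDFLKGRMKAYCMFKCNCNAGI
EDRNGKRVTVGERTILRKGNDCLCVKQFLKECINGPELLRTKMVRDKSWWDPFLFSQNVK
FTKDRTQGEMILRRTLIRASYALRLPLGTVSTTNERRAVLLEDVTEDCFVSRADLTTIYI
ALEADAHHFPIAHKGFAVGQEAVYISEGLNCNGSLEKPTRTIMIPDAYDKKAKSTNGLLQ
DDIDAVRDVCVQAKSLTSLMVLGPVFQPNDSIIAYRPANAVYATIVRKQKEVEMSEETSK
GHLESCYDNHPPIPVLEDIPTILAKVAVLEVSRPNDMHGLEVAYSFKSIYSTDALTIAPF
AEEKVGEDYYELIRPTLVSQIGVVKITCLVSWVCPAGLKRCLISGVPLVGQVLQPELLSV
VGVWCSVVGSPTANRHARSGQTAHLPYLGACSPSMERELVEVTFHDTIAYGKKLRIPVRR
VTYETPVYAETRVDSVAWELITNTKRSSKKKMGTFRPSPALPFCVGCTAHILTYTFLVFI
VYRQLAKAAAEELNAQAIVFQSVRFATELCLALAYREIHWLYPYELEEQVLTDFLQQFNK
YVLTFASYNIKNLEAAGFAKVKGYINVWKRQLNALPFEEIEPYYMGTQQHEDSPGGFNPE
GATEYVTVEKNWNLISIAERRANMQLVHGLFKEALSWYIHENPTRLGMGSSVVQLKFPEF
FRVSMALMFKRLILGLNPSTIPDEESGLPFAGRLIKVQPKENPEDANIVLSDAGFQHSLG
FVSIAED
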