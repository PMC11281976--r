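abbreviation,name,kind,units,description
BL,Basilar length,linear,mm,Distance between the basion and the most anterior point of the palate between the incisors on the midline in ventral view
SBL,Skull base length,linear,mm,Distance between the basion and the most posterior point of the palate on the midline in ventral view
PL,Palatal length,linear,mm,Distance between the most posterior point of the palate and the most anterior point of the palate between the incisors on the midline in ventral view
MDL,Maxillary diastemal length,linear,mm,Distance between the most mesial point of the left toothrow at the alveolar base (P2) and the most labio-distal point of the upper third incisor (I3) at the alveolar base in ventral view
PW,Premaxillary width,linear,mm,Distance between the most labio-distal points of the left and right third incisors (I3) at the alveolar base in ventral view
SI,Supraorbital interdistance,linear,mm,Distance between the most medial points of the left and right supraorbital foramina in dorsal view
CRL,Cranial roof length,linear,mm,Distance between the occipital protuberance and the nasion on the midline in dorsal view
FL,Facial length,linear,mm,Distance between the nasion and the prosthion on the midline in dorsal view
SW,Snout width,linear,mm,Distance between the most anterior points of the facial crests in dorsal view
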