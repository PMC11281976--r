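abbreviation,name,kind,units,description
MBW,Maximal braincase width,linear,mm,Distance between the most lateral points on each side of the cerebrum in dorsal view
MBL,Maximal braincase length,linear,mm,Distance between the most posterior point of the cerebellum and the most anterior point of the olfactory bulbs in dorsal view
MCL,Maximal cerebrum length,linear,mm,Distance between the most posterior and anterior points of the cerebrum in lateral view
MBH,Maximal braincase height,linear,mm,Distance between the most ventral point of the medulla oblongata and the most dorsal point of the cerebrum in lateral view
MCH,Maximal cerebrum height,linear,mm,Distance between the most ventral and dorsal points of the cerebrum in lateral view
OBW,Olfactory bulbs width,linear,mm,Distance between the most lateral points of the contact between olfactory bulbs and cerebrum in ventral view
MICW,Minimal intercanal complex width,linear,mm,Distance between the points of maximal concave curvature on each lateral border of the intercanal complex in ventral view
MCW,Maximal cerebellum width,linear,mm,Distance between the most lateral points on each side of the cerebellum in occipital view
OBH,Olfactory bulbs height,linear,mm,Distance between the most ventral and dorsal points of the contact between the olfactory bulbs and the cerebrum
IHA,Intersphenorbital-hypophyseal angle,angle,degrees,Deviation of the medial edge of the sphenorbital fissures from the notch of the hypophyseal region in ventral view
HPA,Hypophyseal-pons angle,angle,degrees,Posteroventral orientation of the pons with respect to the ventral plane of the hypophyseal region in lateral view
CSA,Cerebellum-spinal cord angle,angle,degrees,Posterior plane of the cerebellum with respect to the plane formed by the spinal cord in lateral view
OFA,Olfactory bulbs-frontal lobe angle,angle,degrees,Posterior plane of the olfactory bulbs with respect to the anterior plane of the frontal lobe in lateral view
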