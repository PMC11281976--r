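abbreviation,name,kind,units,description
C0,Length of the cochlea,linear,mm,From the cochlear apex to the base of the oval window
C1,Length of the lateral semicircular canal,linear,mm,From the junction between lateral and posterior semicircular canals to the base of the lateral ampulla
C2,Length of the anterior semicircular canal,linear,mm,From the base of the anterior ampulla to the intersection point of the anterior and posterior canals
C3,Length of the posterior semicircular canal,linear,mm,From the intersection point of the anterior and posterior canals to the base of the posterior ampulla
BLL,Bony labyrinth length,linear,mm,Overall inner-ear size proxy: from the cochlear apex to the top of the crus commune
CCL,Crus commune length,linear,mm,From the intersection point of the anterior and posterior canals to the attachment site of cranial nerve VII
CCC,Crus commune circumference,linear,mm,Circumference of the crus commune with the intersection point as start and end point
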