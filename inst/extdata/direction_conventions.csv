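component,injured_side,sign,label
TRANS_X,LEFT,+,lateral
TRANS_X,LEFT,-,medial
TRANS_X,RIGHT,+,medial
TRANS_X,RIGHT,-,lateral
TRANS_Y,LEFT,+,cephalad
TRANS_Y,LEFT,-,caudad
TRANS_Y,RIGHT,+,cephalad
TRANS_Y,RIGHT,-,caudad
TRANS_Z,LEFT,+,anterior
TRANS_Z,LEFT,-,posterior
TRANS_Z,RIGHT,+,anterior
TRANS_Z,RIGHT,-,posterior
ROT_SAGITTAL,LEFT,+,flexion
ROT_SAGITTAL,LEFT,-,extension
ROT_SAGITTAL,RIGHT,+,flexion
ROT_SAGITTAL,RIGHT,-,extension
ROT_AXIAL,LEFT,+,external
ROT_AXIAL,LEFT,-,internal
ROT_AXIAL,RIGHT,+,internal
ROT_AXIAL,RIGHT,-,external
ROT_CORONAL,LEFT,+,adduction
ROT_CORONAL,LEFT,-,abduction
ROT_CORONAL,RIGHT,+,abduction
ROT_CORONAL,RIGHT,-,adduction
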