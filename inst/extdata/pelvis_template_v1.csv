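landmark,side,x_mm,y_mm,z_mm
ASIS,LEFT,115,-15,75
ASIS,RIGHT,-115,-15,75
ISCHIAL_TUBEROSITY,LEFT,55,-140,10
ISCHIAL_TUBEROSITY,RIGHT,-55,-140,10
SUPERIOR_ILIAC_WING,LEFT,95,40,10
SUPERIOR_ILIAC_WING,RIGHT,-95,40,10
ANTERIOR_SI_JOINT_ILIAC,LEFT,35,-5,30
ANTERIOR_SI_JOINT_ILIAC,RIGHT,-35,-5,30
SACRAL_ENDPLATE_CENTER,MIDLINE,0,0,0
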