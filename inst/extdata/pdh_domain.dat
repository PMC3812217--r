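-ENZREV


-ENZIRREV
R1 R2 R3 R4 R5 R6 R7

-METINT
TPP HE-TPP LA_E AcDHL_E DHA_E PdhD1_FAD PdhD1_FADH2 PdhD2 PdhD2_NAD PdhD2_NADH

-METEXT
Pyr CoA NAD AcCoA CO2 NADH

-CAT
R1 : Pyr + TPP = HE-TPP + CO2 .
R2 : HE-TPP + LA_E = AcDHL_E + TPP .
R3 : AcDHL_E + CoA = AcCoA + DHA_E .
R4 : DHA_E + PdhD1_FAD = LA_E + PdhD1_FADH2 .
R5 : PdhD2 + NAD = PdhD2_NAD .
R6 : PdhD1_FADH2 + PdhD2_NAD = PdhD1_FAD + PdhD2_NADH .
R7 : PdhD2_NADH = PdhD2 + NADH .
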