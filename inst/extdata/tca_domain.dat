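-ENZREV
R18 R21 R25 R28 R29 R31

-ENZIRREV
R1 R2 R3 R4 R5 R6 R7 R8 R9 R10 R11 R12 R13 R14 R15 R16 R17 R19 R20 R22 R23 R24 R26 R27 R30 R32 R33

-METINT
Pyr CoA AcCoA Cit ICit AKG SucCoA Suc Fum Mal OAA TPP HE-TPP HSuc-TPP LA_E AcDHL_E DHA_E LA_Eo SucDHL_E DHA_Eo PdhD1_FAD PdhD1_FADH2 PdhD2 PdhD2_NAD PdhD2_NADH SucC1 SucC1_ADP SucC1_ATP SucD1_CoA SdhA1 SdhA1_FAD SdhA1_FADH2 Mdh1 Mdh1_NAD Mdh1_NADH ywkA2 ywkA2_NAD ywkA2_NADH pyc2 pyc2_ATP pyc2_ADP

-METEXT
Glc AcP CO2 NAD NADH FAD FADH2 ATP ADP SucD1

-CAT
R1 : Pyr + TPP = HE-TPP + CO2 .
R2 : HE-TPP + LA_E = AcDHL_E + TPP .
R3 : AcDHL_E + CoA = AcCoA + DHA_E .
R4 : DHA_E + PdhD1_FAD = LA_E + PdhD1_FADH2 .
R5 : PdhD2 + NAD = PdhD2_NAD .
R6 : PdhD1_FADH2 + PdhD2_NAD = PdhD1_FAD + PdhD2_NADH .
R7 : PdhD2_NADH = PdhD2 + NADH .
R8 : AcCoA + OAA = Cit + CoA .
R9 : Cit = ICit .
R10 : ICit = AKG + CO2 .
R11 : AKG + TPP = HSuc-TPP + CO2 .
R12 : HSuc-TPP + LA_Eo = SucDHL_E + TPP .
R13 : SucDHL_E + CoA = SucCoA + DHA_Eo .
R14 : DHA_Eo + PdhD1_FAD = LA_Eo + PdhD1_FADH2 .
R15 : SucCoA + SucC1_ADP + SucD1 = Suc + SucC1_ATP + SucD1_CoA .
R16 : Suc + SdhA1_FAD = Fum + SdhA1_FADH2 .
R17 : Fum = Mal .
R18 : Mal + Mdh1_NAD = OAA + Mdh1_NADH .
R19 : Mal + ywkA2_NAD = Pyr + CO2 + ywkA2_NADH .
R20 : Pyr + CO2 + pyc2_ATP = OAA + pyc2_ADP .
R21 : AcCoA = AcP + CoA .
R22 : Glc = Pyr .
R23 : SucC1 + ADP = SucC1_ADP .
R24 : SucC1_ATP = SucC1 + ATP .
R25 : SucD1 + CoA = SucD1_CoA .
R26 : SdhA1 + FAD = SdhA1_FAD .
R27 : SdhA1_FADH2 = SdhA1 + FADH2 .
R28 : Mdh1 + NAD = Mdh1_NAD .
R29 : Mdh1_NADH = Mdh1 + NADH .
R30 : ywkA2 + NAD = ywkA2_NAD .
R31 : ywkA2 + NADH = ywkA2_NADH .
R32 : pyc2 + ATP = pyc2_ATP .
R33 : pyc2_ADP = pyc2 + ADP .
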