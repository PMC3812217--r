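{
  "EFM 1": ["R20", "-R18", "R19", "-R28", "-R29", "R30", "-R31", "R32", "R33"],
  "EFM 2": ["R5", "R6", "R7", "R8", "R11", "R12", "R13", "R14", "R9", "R10", "R15", "R16", "R17", "R18", "-R21", "R23", "R24", "-R25", "R26", "R27", "R28", "R29"],
  "EFM 3": ["R5", "R6", "R7", "R8", "R11", "R12", "R13", "R14", "R20", "R9", "R10", "R15", "R16", "R17", "R19", "-R21", "R23", "R24", "-R25", "R26", "R27", "R30", "-R31", "R32", "R33"],
  "EFM 4": ["R1", "R2", "R3", "R4", "R5", "R6", "R7", "R22", "R21"],
  "EFM 5": ["R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R11", "R12", "R13", "R14", "R22", "R9", "R10", "R15", "R16", "R17", "R18", "R23", "R24", "-R25", "R26", "R27", "R28", "R29"],
  "EFM 6": ["R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R11", "R12", "R13", "R14", "R20", "R22", "R9", "R10", "R15", "R16", "R17", "R19", "R23", "R24", "-R25", "R26", "R27", "R30", "-R31", "R32", "R33"]
}
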