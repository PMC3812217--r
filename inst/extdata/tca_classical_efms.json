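{
  "EFM 1": ["pyc", "-mdh", "ywka"],
  "EFM 2": ["citA", "odh", "citB", "icd", "-SucCD", "SucABC", "fumC", "mdh", "-Pta"],
  "EFM 3": ["citA", "pyc", "odh", "citB", "icd", "-SucCD", "SucABC", "fumC", "ywka", "-Pta"],
  "EFM 4": ["pdh", "Glyco", "Pta"],
  "EFM 5": ["pdh", "citA", "odh", "Glyco", "citB", "icd", "-SucCD", "SucABC", "fumC", "mdh"],
  "EFM 6": ["pdh", "citA", "pyc", "odh", "Glyco", "citB", "icd", "-SucCD", "SucABC", "fumC", "ywka"]
}
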