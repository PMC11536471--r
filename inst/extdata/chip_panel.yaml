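version: chipdyn-default-v1 (representative intervals)
capture_mode:
  ASXL1: full-gene
  ASXL2: full-gene
  BRCC3: full-gene
  CBL: full-gene
  DNMT3A: full-gene
  ETNK1: hotspot-region
  GNAS: hotspot-region
  GNB1: hotspot-region
  IDH1: hotspot-region
  IDH2: hotspot-region
  JAK2: hotspot-region
  KIT: hotspot-region
  KRAS: hotspot-region
  MPL: hotspot-region
  NRAS: hotspot-region
  PPM1D: full-gene
  SETBP1: hotspot-region
  SF3B1: full-gene
  SRSF2: hotspot-region
  TET2: full-gene
  TP53: full-gene
  U2AF1: hotspot-region
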