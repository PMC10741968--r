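# Packaged monolayer parameter presets. Each entry carries an explicit unit
# tag; mN/m entries are converted to kBT/nm^2 at load time (default 300 K).
DOPC:
  params:
    B:     {value: 10,     unit: kBT}
    Kt:    {value: 40,     unit: mN/m}
    Ka:    {value: 133,    unit: mN/m}
    KG:    {value: -5,     unit: kBT}
    Krot:  {value: 5,      unit: kBT}
    J0:    {value: -0.091, unit: 1/nm}
    sigma: {value: 0.1,    unit: mN/m}
    h:     {value: 1.45,   unit: nm}
  geometry: {l_p: 5.0, r_p: 0.65}
POPC_POPS_3to1:
  params:
    B:     {value: 11,     unit: kBT}
    Kt:    {value: 40,     unit: mN/m}
    Ka:    {value: 117,    unit: mN/m}
    KG:    {value: -5.5,   unit: kBT}
    Krot:  {value: 5.5,    unit: kBT}
    J0:    {value: 0,      unit: 1/nm}
    sigma: {value: 0.1,    unit: mN/m}
    h:     {value: 1.46,   unit: nm}
  geometry: {l_p: 5.0, r_p: 0.65}
# "Common" lipid inclusion patch: B, J0 and h are meant to be overridden by
# the caller; tilt/compression/tension as DOPC, twist and Gaussian moduli
# fixed at +5/-5 kBT.
inclusion_common:
  params:
    B:     {value: 10,    unit: kBT}
    Kt:    {value: 40,    unit: mN/m}
    Ka:    {value: 133,   unit: mN/m}
    KG:    {value: -5,    unit: kBT}
    Krot:  {value: 5,     unit: kBT}
    J0:    {value: 0,     unit: 1/nm}
    sigma: {value: 0.1,   unit: mN/m}
    h:     {value: 1.45,  unit: nm}
  geometry: {r_lip: 0.5}
# "Thin" lipid inclusion (photoswitchable-lipid-like): monolayer thickness
# 0.7 nm, patch radius 0.662 nm.
inclusion_thin:
  params:
    B:     {value: 10,    unit: kBT}
    Kt:    {value: 40,    unit: mN/m}
    Ka:    {value: 133,   unit: mN/m}
    KG:    {value: -5,    unit: kBT}
    Krot:  {value: 5,     unit: kBT}
    J0:    {value: 0,     unit: 1/nm}
    sigma: {value: 0.1,   unit: mN/m}
    h:     {value: 0.7,   unit: nm}
  geometry: {r_lip: 0.662}
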