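# Halle architecture model knowledge base (expert input, editable).
#
# The prototype centers live in the (P4, P7) feature plane: P4 = largest
# point fraction in any 1 m super-voxel (leaf/branch clustering), P7 =
# occupied-voxel fraction of the stem space (lower third of the crown,
# within half the crown radius of the axis).  The numeric anchors encode
# the qualitative low / moderate / high signatures of the four models on
# the scale this feature pair takes for ~10 points/m2 airborne laser
# scanning crowns; adapt them when working with other sensors or forests.
#
# `models` carries the model-indexed reading of the growth habits (each
# architecture model described in its own terms).  `species_habits` carries
# an alternative species-indexed reading in which some species are paired
# with habit rows that differ from their model's description; the two
# readings are intentionally kept side by side and not reconciled.

feature_pair: [P4, P7]

models:
  Massart:
    trunk: "monopodial, orthotropic trunk with rhythmic growth"
    branches: "plagiotropic, main branches produced in whorls"
    growth: "rhythmic"
    center: [0.029, 0.010]
    signature: "low P4, low P7"
    species_hint: PA
  Rauh:
    trunk: "monopodial, orthotropic, rhythmic growth"
    branches: "orthotropic, morphogenetically equivalent to the trunk"
    growth: "rhythmic"
    center: [0.120, 0.031]
    signature: "high P4, low P7"
    species_hint: PS
  Roux:
    trunk: "monopodial, orthotropic trunk with continuous growth"
    branches: "plagiotropic, monopodial, non-phyllomorphic"
    growth: "continuous"
    center: [0.035, 0.091]
    signature: "moderate P4, low P7"
    species_hint: PT
  Attim:
    trunk: "monopodial, orthotropic, continuous growth"
    branches: "orthotropic, morphogenetically equivalent to the trunk"
    growth: "more or less continuous"
    center: [0.014, 0.164]
    signature: "low-to-moderate P4, high P7"
    species_hint: QR

quadrant:
  thresholds: [0.032, 0.060]
  map:
    low_low: Massart
    high_low: Rauh
    low_high: Attim
    high_high: Roux

species_habits:
  PS:
    trunk: "monopodial, indeterminate"
    branches: "plagiotropic, (main branches) produced in whorls"
    growth: "rhythmic"
  PT:
    trunk: "monopodial"
    branches: "orthotropic, morphogenetically equivalent to the trunk"
    growth: "rhythmic"
  QR:
    trunk: "monopodial, indeterminate"
    branches: "plagiotropic, monopodial, non-phyllomorphic"
    growth: "continuous"
  PA:
    trunk: "monopodial"
    branches: "orthotropic, morphogenetically equivalent to the trunk"
    growth: "more or less continuous"
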