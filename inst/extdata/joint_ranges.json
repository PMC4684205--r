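{
  "_comment": [
    "Joint-range presets in degrees. Dorsoventral (dv) and anteroposterior",
    "(ap) angles are measured from the horizontal / from a line drawn",
    "perpendicular to the long axis of the body, relative to the long axis",
    "of the propodial; positive dv is dorsal, positive ap is anterior.",
    "Rotation (rot) bounds are identical in all presets: +30 supination,",
    "-45 pronation.  The dv/ap endpoints are published only graphically;",
    "these values are back-derived from the achieved optimum ranges and the",
    "printed percentage of available range they used, and are editable."
  ],
  "rotation": {"min": -45, "max": 30},
  "neutral": {
    "fore": {"dv": -15, "ap": -16, "rot": 0},
    "hind": {"dv": -30, "ap": -27, "rot": 0}
  },
  "presets": {
    "narrow": {
      "fore": {"dv": [-25, 30], "ap": [-21, -11]},
      "hind": {"dv": [-35, 2],  "ap": [-57, -27]}
    },
    "medium": {
      "fore": {"dv": [-40, 30], "ap": [-25, 10]},
      "hind": {"dv": [-50, 15], "ap": [-55, -5]}
    },
    "wide": {
      "fore": {"dv": [-80, 30], "ap": [-45, 15]},
      "hind": {"dv": [-80, 30], "ap": [-60, 10]}
    }
  }
}
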