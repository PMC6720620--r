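{
  "description": "Wet-season (November) coupled NDVI x BBST rule set for the grassland-shrubland-woodland continuum. One-sided bounds are strict; interval bounds are inclusive. Classes are tested in precedence order and the first full match wins; pixels matching no rule stay unclassified.",
  "precedence": ["woodland", "grassland", "shrubland"],
  "rules": {
    "woodland": {
      "ndvi": {"min": 0.41, "min_inclusive": false},
      "bbst": {"max": 36.5, "max_inclusive": false}
    },
    "grassland": {
      "ndvi": {"max": 0.36, "max_inclusive": false},
      "bbst": {"min": 38.6, "min_inclusive": false}
    },
    "shrubland": {
      "ndvi": {"min": 0.28, "max": 0.51, "min_inclusive": true, "max_inclusive": true},
      "bbst": {"min": 36.7, "max": 39.3, "min_inclusive": true, "max_inclusive": true}
    }
  }
}
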