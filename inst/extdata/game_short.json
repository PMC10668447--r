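{
  "levels": [
    {
      "name": "tutorial",
      "ring_eccentricities": 15,
      "elements_per_ring": 8,
      "min_duration_min": 0.5,
      "depth_radii_m": 2,
      "has_trials": true
    },
    {
      "name": "axes",
      "ring_eccentricities": [12.5, 25, 37.5, 50],
      "elements_per_ring": 2,
      "min_duration_min": 3,
      "depth_radii_m": 2,
      "has_trials": true
    },
    {
      "name": "stimuli",
      "ring_eccentricities": 15,
      "elements_per_ring": 8,
      "min_duration_min": 4.5,
      "depth_radii_m": 2,
      "has_trials": true
    },
    {
      "name": "depth",
      "ring_eccentricities": 15,
      "elements_per_ring": 8,
      "min_duration_min": 6,
      "depth_radii_m": [2, 4],
      "has_trials": true
    },
    {
      "name": "full_field",
      "ring_eccentricities": [12.5, 25, 37.5, 50],
      "elements_per_ring": 6,
      "min_duration_min": 4.5,
      "depth_radii_m": 2,
      "has_trials": true
    },
    {
      "name": "free_viewing",
      "ring_eccentricities": [],
      "elements_per_ring": 0,
      "min_duration_min": 1,
      "depth_radii_m": 2,
      "has_trials": false
    }
  ],
  "grid": {
    "radial_spacing": 12.5,
    "within_ring_spacing": 15,
    "radius": 2
  }
}
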