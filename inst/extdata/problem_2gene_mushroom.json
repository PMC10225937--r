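{
  "schema": "bifdesign-problem/1",
  "n_genes": 2,
  "signal_mask": [true, true],
  "y_lower": [
    [
      -1,
      -1
    ],
    [
      -1,
      -1
    ]
  ],
  "y_upper": [
    [
      1,
      1
    ],
    [
      1,
      1
    ]
  ],
  "x_lower": {
    "p0": 10,
    "p1": 1,
    "p2": 10,
    "k": 0.001,
    "R1": 50,
    "R2": 50,
    "dv": 0.1,
    "K1": 1,
    "K2": 1
  },
  "x_upper": {
    "p0": 2000,
    "p1": 500,
    "p2": 2000,
    "k": 1,
    "R1": 500,
    "R2": 500,
    "dv": 10,
    "K1": 300,
    "K2": 300
  },
  "boxes": [
    {
      "s_interval": [0.5, 60],
      "omega_box": [
        [
          0.01,
          300
        ],
        [
          0.01,
          800
        ]
      ]
    },
    {
      "s_interval": [5, 1500],
      "omega_box": [
        [
          0.01,
          300
        ],
        [
          0.01,
          800
        ]
      ]
    }
  ],
  "n_folds": 4,
  "target_label": "mushroom",
  "objectives": "psi",
  "s_range": [0.1, 5000],
  "s_points": 90,
  "n_runs": 2000,
  "seed": 1
}
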