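[
  {
    "species": "A_marina",
    "component": "above_ground",
    "predictor": "height",
    "form": "power",
    "a": 1.266524,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "A_marina",
    "component": "below_ground",
    "predictor": "height",
    "form": "power",
    "a": 0.878335,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "A_corniculatum",
    "component": "above_ground",
    "predictor": "height",
    "form": "power",
    "a": 0.184453,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "A_corniculatum",
    "component": "below_ground",
    "predictor": "height",
    "form": "power",
    "a": 0.074349,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "R_stylosa",
    "component": "above_ground",
    "predictor": "height",
    "form": "power",
    "a": 1.222253,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "R_stylosa",
    "component": "below_ground",
    "predictor": "height",
    "form": "power",
    "a": 0.425954,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "B_gymnorrhiza",
    "component": "above_ground",
    "predictor": "height",
    "form": "power",
    "a": 2.691932,
    "b": 2,
    "carbon_factor": 0.46
  },
  {
    "species": "B_gymnorrhiza",
    "component": "below_ground",
    "predictor": "height",
    "form": "power",
    "a": 0.956907,
    "b": 2,
    "carbon_factor": 0.46
  }
]
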