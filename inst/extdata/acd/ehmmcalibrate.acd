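application: ehmmcalibrate [
  documentation: "Calibrate HMM search statistics"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  infile: hmmfile [
    parameter: "Y"
    information: "HMM file to calibrate"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  histfile: histogram [
    additional: "Y"
    knowntype: "hmmer histogram"
  ]

  outfile: outfile [
    parameter: "Y"
    knowntype: "hmmcalibrate output"
  ]

endsection: output
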