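application: ehmmfetch [
  documentation: "Retrieve an HMM from an HMM database"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  string: name [
    parameter: "Y"
    information: "Name of the HMM to fetch"
    relations: "EDAM: 1000010 ! HMMER hidden Markov model identifier"
  ]

  infile: database [
    parameter: "Y"
    information: "HMM database file"
    relations: "EDAM: HMMER hidden Markov model database"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "hmm"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: output
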