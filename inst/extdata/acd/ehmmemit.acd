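application: ehmmemit [
  documentation: "Generate sequences from a profile HMM"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  infile: hmmfile [
    parameter: "Y"
    information: "Profile HMM to emit from"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "hmmemit output"
  ]

endsection: output
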