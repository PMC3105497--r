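application: ehmmbuild [
  documentation: "Build a profile HMM from an alignment"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqset: alignfile [
    parameter: "Y"
    type: "gapprotein"
    aligned: "Y"
    relations: "EDAM: Protein sequence alignment data"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: hmmfile [
    parameter: "Y"
    knowntype: "hmm"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: output
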