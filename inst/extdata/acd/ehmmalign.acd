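application: ehmmalign [
  documentation: "Align sequences to an HMM profile"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqset: seqs [
    parameter: "Y"
    type: "protein"
    relations: "EDAM: 1000004 ! Protein sequence record"
  ]

  infile: hmmfile [
    parameter: "Y"
    information: "HMM profile file"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  align: align [
    parameter: "Y"
    aformat: "fasta"
  ]

endsection: output
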