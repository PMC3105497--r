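application: ehmmindex [
  documentation: "Create a binary SSI index for an HMM database"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  infile: database [
    parameter: "Y"
    information: "HMM database file to index"
    relations: "EDAM: HMMER hidden Markov model database"
  ]

endsection: input
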