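application: showpep [
  documentation: "Displays protein sequences with features in pretty format"
  groups: "Display"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqall: sequence [
    parameter: "Y"
    type: "protein"
    features: "Y"
    relations: "EDAM: 1000004 ! Protein sequence record"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "showpep output"
  ]

endsection: output
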