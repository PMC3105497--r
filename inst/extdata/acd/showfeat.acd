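application: showfeat [
  documentation: "Display features of a sequence in pretty format"
  groups: "Display"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqall: sequence [
    parameter: "Y"
    type: "any"
    features: "Y"
    relations: "EDAM: 1000003 ! Sequence record"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "showfeat output"
  ]

endsection: output
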