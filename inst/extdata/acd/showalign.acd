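application: showalign [
  documentation: "Display a multiple sequence alignment in pretty format"
  groups: "Display"
  relations: "EDAM: 2000004 ! Sequence visualisation"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqset: alignment [
    parameter: "Y"
    type: "gapany"
    aligned: "Y"
    relations: "EDAM: Sequence alignment data"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "showalign output"
  ]

endsection: output
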