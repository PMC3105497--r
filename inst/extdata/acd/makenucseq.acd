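application: makenucseq [
  documentation: "Create random nucleotide sequences"
  groups: "Edit"
]

section: output [
  information: "Output section"
  type: "page"
]

  seqoutall: seqoutall [
    parameter: "Y"
    relations: "EDAM: 1000003 ! Sequence record"
  ]

endsection: output
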