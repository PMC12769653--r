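{
  "face": [[760, 240], [1160, 240], [1160, 640], [760, 640], [760, 240]],
  "text_box": [[200, 760], [1720, 760], [1720, 960], [200, 960], [200, 760]]
}
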