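{
  "s": 30,
  "r": 1,
  "u": 2970,
  "v": 30,
  "d": 1,
  "switching": { "form": "hill", "a": 1e8, "h": 4 }
}
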