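{
  "required": {
    "arm": "string",
    "config": {
      "method": "string",
      "stabilize": "boolean",
      "period_p": "number",
      "lambda_red": "number",
      "threshold_conventional": "number",
      "threshold_dnn": "number",
      "median_kernel": "number",
      "min_fraction": "number",
      "angle_tolerance": "number",
      "max_capillaries": "number",
      "min_area": "number",
      "channel": "string",
      "seed": "number"
    },
    "video": {
      "n_frames": "number",
      "height": "number",
      "width": "number",
      "fps": "number",
      "source": "string"
    },
    "capillaries": "list"
  }
}
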