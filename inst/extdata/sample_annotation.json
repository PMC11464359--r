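{
  "version": "5.2.1",
  "flags": {},
  "imagePath": "plot_15m_001.png",
  "imageHeight": 100,
  "imageWidth": 100,
  "shapes": [
    {
      "label": "sorghum",
      "points": [[10.0, 10.0], [30.0, 30.0]],
      "shape_type": "rectangle",
      "group_id": null
    },
    {
      "label": "sorghum",
      "points": [[80.0, 55.0], [60.0, 35.0]],
      "shape_type": "rectangle",
      "group_id": null
    }
  ]
}
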