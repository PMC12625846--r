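[
  {"name": "m01_TbBMR_brain.Tb",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["Ta","Tb"],["Tb","BMR"],["Tb","brain"]]},
  {"name": "m02_TbBMR_brain.BMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["Ta","Tb"],["Tb","BMR"],["BMR","brain"]]},
  {"name": "m03_TbBMR_brain.TaTb",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["Ta","Tb"],["Tb","BMR"],["Ta","brain"],["Tb","brain"]]},
  {"name": "m04_TbBMR_brain.TbBMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["Ta","Tb"],["Tb","BMR"],["Tb","brain"],["BMR","brain"]]},
  {"name": "m05_TbBMR_brain.TaTbBMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["Ta","Tb"],["Tb","BMR"],["Ta","brain"],["Tb","brain"],["BMR","brain"]]},
  {"name": "m06_BMRTb_brain.Tb",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["BMR","Tb"],["Tb","brain"]]},
  {"name": "m07_BMRTb_brain.BMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["BMR","Tb"],["BMR","brain"]]},
  {"name": "m08_BMRTb_brain.TaTb",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["BMR","Tb"],["Ta","brain"],["Tb","brain"]]},
  {"name": "m09_BMRTb_brain.TbBMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["BMR","Tb"],["Tb","brain"],["BMR","brain"]]},
  {"name": "m10_BMRTb_brain.TaTbBMR",
   "edges": [["body","NM"],["NM","brain"],["Ta","BMR"],["BMR","Tb"],["Ta","brain"],["Tb","brain"],["BMR","brain"]]}
]
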