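sample,outcome,predictor,selection_count
full,depressive,M,21
full,depressive,SD,15
full,depressive,dev15,0
full,depressive,dev16,5
full,depressive,dev17,1
full,depressive,dev18,3
full,depressive,dev19,9
full,depressive,dev20,3
full,depressive,dev21,5
full,depressive,dev22,1
full,depressive,dev23,0
full,depressive,dev24,0
full,depressive,dev25,5
full,depressive,dev26,4
full,depressive,dev27,2
full,depressive,dev28,0
full,depressive,dev29,3
full,depressive,dev30,0
full,depressive,dev31,4
full,depressive,dev32,0
full,depressive,dev33,1
full,depressive,dev34,0
full,depressive,dev35,0
full,depressive,dev36,3
full,depressive,dev37,1
full,depressive,dev38,3
full,depressive,dev39,4
full,depressive,dev40,6
full,depressive,dev41,1
aces_high,depressive,M,19
aces_high,depressive,SD,12
aces_high,depressive,dev15,7
aces_high,depressive,dev16,8
aces_high,depressive,dev17,2
aces_high,depressive,dev18,3
aces_high,depressive,dev19,3
aces_high,depressive,dev20,12
aces_high,depressive,dev21,3
aces_high,depressive,dev22,0
aces_high,depressive,dev23,0
aces_high,depressive,dev24,2
aces_high,depressive,dev25,0
aces_high,depressive,dev26,21
aces_high,depressive,dev27,1
aces_high,depressive,dev28,2
aces_high,depressive,dev29,1
aces_high,depressive,dev30,0
aces_high,depressive,dev31,0
aces_high,depressive,dev32,2
aces_high,depressive,dev33,0
aces_high,depressive,dev34,0
aces_high,depressive,dev35,1
aces_high,depressive,dev36,1
aces_high,depressive,dev37,1
aces_high,depressive,dev38,0
aces_high,depressive,dev39,2
aces_high,depressive,dev40,0
aces_high,depressive,dev41,3
aces_low,depressive,M,21
aces_low,depressive,SD,1
aces_low,depressive,dev15,4
aces_low,depressive,dev16,4
aces_low,depressive,dev17,2
aces_low,depressive,dev18,2
aces_low,depressive,dev19,7
aces_low,depressive,dev20,2
aces_low,depressive,dev21,1
aces_low,depressive,dev22,0
aces_low,depressive,dev23,0
aces_low,depressive,dev24,4
aces_low,depressive,dev25,5
aces_low,depressive,dev26,0
aces_low,depressive,dev27,2
aces_low,depressive,dev28,0
aces_low,depressive,dev29,0
aces_low,depressive,dev30,1
aces_low,depressive,dev31,1
aces_low,depressive,dev32,1
aces_low,depressive,dev33,0
aces_low,depressive,dev34,2
aces_low,depressive,dev35,2
aces_low,depressive,dev36,0
aces_low,depressive,dev37,0
aces_low,depressive,dev38,1
aces_low,depressive,dev39,3
aces_low,depressive,dev40,1
aces_low,depressive,dev41,1
full,anxiety,M,21
full,anxiety,SD,0
full,anxiety,dev15,2
full,anxiety,dev16,1
full,anxiety,dev17,1
full,anxiety,dev18,0
full,anxiety,dev19,1
full,anxiety,dev20,1
full,anxiety,dev21,0
full,anxiety,dev22,0
full,anxiety,dev23,1
full,anxiety,dev24,1
full,anxiety,dev25,2
full,anxiety,dev26,1
full,anxiety,dev27,6
full,anxiety,dev28,0
full,anxiety,dev29,0
full,anxiety,dev30,0
full,anxiety,dev31,0
full,anxiety,dev32,0
full,anxiety,dev33,0
full,anxiety,dev34,0
full,anxiety,dev35,0
full,anxiety,dev36,0
full,anxiety,dev37,0
full,anxiety,dev38,1
full,anxiety,dev39,0
full,anxiety,dev40,1
full,anxiety,dev41,2
aces_high,anxiety,M,20
aces_high,anxiety,SD,2
aces_high,anxiety,dev15,3
aces_high,anxiety,dev16,6
aces_high,anxiety,dev17,4
aces_high,anxiety,dev18,2
aces_high,anxiety,dev19,0
aces_high,anxiety,dev20,5
aces_high,anxiety,dev21,3
aces_high,anxiety,dev22,1
aces_high,anxiety,dev23,3
aces_high,anxiety,dev24,3
aces_high,anxiety,dev25,1
aces_high,anxiety,dev26,21
aces_high,anxiety,dev27,3
aces_high,anxiety,dev28,1
aces_high,anxiety,dev29,6
aces_high,anxiety,dev30,5
aces_high,anxiety,dev31,7
aces_high,anxiety,dev32,5
aces_high,anxiety,dev33,5
aces_high,anxiety,dev34,3
aces_high,anxiety,dev35,6
aces_high,anxiety,dev36,0
aces_high,anxiety,dev37,3
aces_high,anxiety,dev38,1
aces_high,anxiety,dev39,1
aces_high,anxiety,dev40,2
aces_high,anxiety,dev41,4
aces_low,anxiety,M,21
aces_low,anxiety,SD,0
aces_low,anxiety,dev15,4
aces_low,anxiety,dev16,1
aces_low,anxiety,dev17,1
aces_low,anxiety,dev18,0
aces_low,anxiety,dev19,0
aces_low,anxiety,dev20,0
aces_low,anxiety,dev21,1
aces_low,anxiety,dev22,0
aces_low,anxiety,dev23,0
aces_low,anxiety,dev24,4
aces_low,anxiety,dev25,0
aces_low,anxiety,dev26,1
aces_low,anxiety,dev27,4
aces_low,anxiety,dev28,0
aces_low,anxiety,dev29,0
aces_low,anxiety,dev30,1
aces_low,anxiety,dev31,0
aces_low,anxiety,dev32,1
aces_low,anxiety,dev33,3
aces_low,anxiety,dev34,0
aces_low,anxiety,dev35,1
aces_low,anxiety,dev36,0
aces_low,anxiety,dev37,0
aces_low,anxiety,dev38,1
aces_low,anxiety,dev39,0
aces_low,anxiety,dev40,0
aces_low,anxiety,dev41,1
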