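trial,species,marked,detected,n_videos
1,Heliconius erato,16,16,331
1,Heliconius melpomene,16,12,180
1,Heliconius sara,14,12,718
1,Dryas iulia,12,11,283
2,Heliconius erato,19,15,166
2,Heliconius melpomene,13,9,45
2,Dryadula phaetusa,11,5,92
2,Dryas iulia,11,6,27
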