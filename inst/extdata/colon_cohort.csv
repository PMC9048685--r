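sample_id,gender,age,site,stage,grade,tils
S061,F,75,right colon,II,G2,0
S085,M,75,right colon,III,G2,20
S097,F,64,right colon,II,G3,0
S099,F,77,right colon,III,G2,0
S103,F,62,left colon,III,G2,0
S107,F,88,right colon,II,G2,0
S109,F,65,left colon,III,G2,0
S111,M,77,right colon,I,G2,0
S119,M,76,right colon,I,G2,5
S121,M,79,right colon,II,G2,20
S125,M,75,right colon,I,G3,10
S131,M,72,right colon,I,G1,0
S135,F,87,right colon,II,G3,50
S141,M,51,left colon,I,G1,0
S143,M,70,left colon,IV,G2,5
S145,F,80,left colon,III,G3,0
S147,F,79,right colon,III,G3,60
S151,M,75,left colon,III,G2,5
S157,M,77,right colon,II,G3,0
S161,M,66,left colon,III,G2,10
S165,F,33,left colon,IV,G3,5
S175,M,66,left colon,III,G2,10
S181,M,74,right colon,III,G2,0
S183,M,83,right colon,I,G2,50
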