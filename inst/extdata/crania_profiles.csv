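id,mandible,tooth_stage,hefner,ossa_class,cranio,sex_sa_white,sex_sa_black,sex_walker,sex_cranio,y_hg,mt_hg,pca_continent,snp_count
003,,G,African(0.85),Black,West Africa(0.67),F/M,M,M,M(0.93),B2a1a1a1,L3e (L3b1b),Africa,51100
028,,F,European(0.87),White,Somali(0.97),F/M,F,F/M,F(0.95),J1a2a1a,L2a (L2a1+143+16189 (16192)),Africa,30842
058 A1,X,Adult,European(0.51),White,Somali(0.58),F/M,M,M,M(0.72),E1b1b1b2a1a1a1a,T1a,Africa,163213
062,X,G,African(0.99),Black,West Africa(0.91),M,M,M,M(0.82),E1a2a,L3b (L3b1a+@16124),Africa,406751
095,,Adult,African(0.80),White,Portuguese(0.86),F,M,M,M(0.77),E1b1b1b1b1a,L2c (L2c),Africa,128947
099,,Adult,European(0.99),White,West Africa(0.41),F,M,M,M(0.69),A1b1b2b2~,L3i,Africa,197047
100-1,X,Adult,European(0.95),White,Somali(0.96),F,F,F,F(0.98),E1b1a1a1a1c2c3a1b,L3b (L3b1a),Africa,184076
100-2,X,Adult,European(0.96),White,Hainan(0.41),M/F,M,M,M(0.97),E1b1b1a1a1b1a,L0a (L0a1a+200),Africa,124672
104-1,,Adult,African(0.98),Black,West Africa(0.73),F/M,M,M/F,M/F(0.51),J1a2a1a2d2b2b2c4d2a2a5a1c,L5b (L5b1),Africa,140034
104-5,,F,African(0.59),Black,Somali(0.92),F,F,F,F(0.91),A1b1b2b~,U2d (U2d),Africa,89217
105-2,X,F,African(0.65),White,West Africa(0.32),M,M,M,M(0.99),E1b1a1a1a1c1b2a,L3e (L3e2a),Africa,205032
125,,Adult,European(0.47),White,Somali(0.38),F/M,M,M,F/M(0.51),J1a2a1a1a,L3i (L3i2),Africa,177666
131,X,Adult,European(0.69),White,Zulu(0.24),M/F,M/F,M/F,M(0.75),E1b1a1a1a1c2~,L2a (L2a1c),Africa,561124
137,X,Adult,European(0.84),White,Somali(0.98),F/M,M,M,M(0.74),E1b1b1b2a1a1a1a1a~,L2a (L2a1j),Africa,147779
146,,Adult,European(0.84),White,West Africa(0.33),M,M,M,M(0.93),J1a2a1a2d2b2b2c4d1a1a1,L2a (L2a1c),Africa,224868
149-1,X,G,European(0.99),White,Euro-American(0.31),M/F,M/F,M,M(0.99),E1b1b1a1a1b1,L3x (L3x1b),Africa,580917
154-1,X,F,African(0.95),Black,Somali(0.48),F/M,M/F,M,F(0.76),E1b1a1a1a1c2c3a2a,L2a (L2a1c),Africa,139467
154-2,X,Adult,African(0.99),Black,Somali(0.70),M,M,M,M(0.99),E1b1a1a1a1c1b,L3f (L3f1b4a),Africa,164138
178-1,X,Adult,Asian(0.34),Black,Somali(0.42),M/F,M,M,M(0.75),E1a2b1a2,L3b (L3b1a+@16124),Africa,165037
178-2,,Adult,Asian(0.49),White,West Africa(0.42),M,M,M,F(0.99),E1a2b1a2,L3b (L3b1a+@16124),Africa,66289
178-3,,Adult,Asian(0.73),White,Somali(0.47),F,F,F,F(0.59),E1b1a1a1a1c2,L2a1a1,Africa,188702
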