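optimizer,fold,features,n_estimators,learning_rate,max_depth,min_child_weight
gjo,1,5 6 7 11 14 23 27 32 34 38 41,279,0.116176736,7,1
gjo,2,5 10 15 20 32 34 39 41,299,0.110572987,7,1
gjo,3,6 8 10 20 21 27 30 32 36,272,0.084533705,7,1
gjo,4,6 7 10 14 20 30 32 34 45 47,186,0.126345040,7,1
gjo,5,5 7 10 14 15 34 45,253,0.193675087,7,1
gjo,6,5 7 8 10 23 24 34 41,274,0.123926983,7,1
gjo,7,1 8 14 20 21 23 34,280,0.179786016,7,1
gjo,8,5 10 14 24 34 45,266,0.132827173,7,1
gjo,9,5 6 14 20 23 32 34 36 41 45,280,0.099581423,7,1
gjo,10,5 14 20 27 32 34 38 41,278,0.143630097,7,1
warso,1,1 5 16 17 18 21 22 23 24 25 29 30 35 36 40 41 44 46,225,0.171671644,6,8
warso,2,1 5 15 16 17 21 23 25 26 29 30 32 35 36 37 40 41 44 46,219,0.177963083,5,2
warso,3,13 16 21 23 24 25 29 30 32 35 37 41 43 46,233,0.200000000,6,8
warso,4,1 5 6 15 16 17 18 23 24 25 26 27 28 29 30 35 36 40 41 43 44 46,214,0.200000000,6,7
warso,5,5 15 16 17 18 21 23 24 25 26 29 30 35 36 40 41 43 44 46,254,0.177088074,6,9
warso,6,1 5 15 16 17 18 21 23 24 25 29 30 35 36 40 41 43 44 46,230,0.200000000,6,8
warso,7,1 4 5 6 7 8 9 10 11 15 16 17 26 30 31 33 38 39 40 42 43 44 47,208,0.200000000,4,2
warso,8,2 5 9 10 11 13 14 16 31 32 33 34 36 38 40 44 46 47,211,0.172988329,6,2
warso,9,2 5 8 11 15 18 21 22 23 24 25 26 29 30 31 38 40 41 43,230,0.130140028,5,2
warso,10,1 9 11 12 13 15 16 21 24 25 26 32 35 36 37 38 40 41 43 44 45,211,0.200000000,6,7
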