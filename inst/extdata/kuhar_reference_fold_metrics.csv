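optimizer,fold,test_accuracy,test_fscore,test_precision,test_recall,auc
gjo,1,93.54,92.28,93.18,91.58,0.99675
gjo,2,93.41,92.02,92.72,91.44,0.99715
gjo,3,93.93,92.82,93.42,92.32,0.99754
gjo,4,93.35,91.93,92.37,91.60,0.99729
gjo,5,93.67,92.39,92.92,91.98,0.99663
gjo,6,93.77,92.34,92.52,92.19,0.99736
gjo,7,93.67,91.85,92.28,91.48,0.99816
gjo,8,93.35,92.16,93.06,91.46,0.99724
gjo,9,93.43,92.16,93.20,91.40,0.99703
gjo,10,93.38,92.46,93.13,91.91,0.99579
warso,1,94.17,93.03,93.84,92.39,0.99712
warso,2,94.47,93.54,94.04,93.12,0.99717
warso,3,94.23,93.06,93.57,92.62,0.99736
warso,4,93.72,92.47,92.72,92.32,0.99710
warso,5,93.98,92.75,93.25,92.35,0.99718
warso,6,93.65,92.28,92.79,91.85,0.99754
warso,7,93.83,92.15,92.69,91.71,0.99805
warso,8,93.88,92.97,93.46,92.55,0.99651
warso,9,94.23,93.24,94.22,92.52,0.99639
warso,10,94.07,93.28,94.11,92.61,0.99547
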