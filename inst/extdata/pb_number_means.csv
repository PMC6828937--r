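time_h,marker,mean
8,GE-1/HEDLS,233.90
12,GE-1/HEDLS,193.19
16,GE-1/HEDLS,149.42
20,GE-1/HEDLS,222.16
24,GE-1/HEDLS,215.81
28,GE-1/HEDLS,518.41
32,GE-1/HEDLS,334.35
36,GE-1/HEDLS,152.55
40,GE-1/HEDLS,243.39
44,GE-1/HEDLS,303.24
48,GE-1/HEDLS,328.19
52,GE-1/HEDLS,257.67
56,GE-1/HEDLS,265.86
60,GE-1/HEDLS,194.10
64,GE-1/HEDLS,159.11
68,GE-1/HEDLS,260.99
8,DDX6,158.50
12,DDX6,135.88
16,DDX6,107.21
20,DDX6,228.78
24,DDX6,188.79
28,DDX6,326.62
32,DDX6,322.07
36,DDX6,217.18
40,DDX6,440.14
44,DDX6,441.96
48,DDX6,458.20
52,DDX6,343.16
56,DDX6,436.80
60,DDX6,330.72
64,DDX6,318.47
68,DDX6,399.98
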