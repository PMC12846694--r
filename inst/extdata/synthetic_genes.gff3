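##gff-version 3
##sequence-region 1 1 100000000
##sequence-region 2 1 100000000
# Synthetic gene models for pipeline demonstrations and tests; coordinates
# match the simulator's two 100-Mb chromosomes. Not a real annotation.
1	synthetic	gene	4950000	5050000	.	+	.	ID=SYNG0001;Name=SYNG0001
1	synthetic	gene	10200000	10400000	.	-	.	ID=SYNG0002;Name=SYNG0002
1	synthetic	gene	20000000	20150000	.	+	.	ID=SYNG0003;Name=SYNG0003
1	synthetic	gene	33500000	33700000	.	+	.	ID=SYNG0004;Name=SYNG0004
1	synthetic	gene	52000000	52100000	.	-	.	ID=SYNG0005;Name=SYNG0005
1	synthetic	gene	74000000	74250000	.	+	.	ID=SYNG0006;Name=SYNG0006
1	synthetic	gene	91000000	91080000	.	-	.	ID=SYNG0007;Name=SYNG0007
2	synthetic	gene	3000000	3120000	.	+	.	ID=SYNG0008;Name=SYNG0008
2	synthetic	gene	15000000	15200000	.	-	.	ID=SYNG0009;Name=SYNG0009
2	synthetic	gene	28000000	28100000	.	+	.	ID=SYNG0010;Name=SYNG0010
2	synthetic	gene	44000000	44300000	.	+	.	ID=SYNG0011;Name=SYNG0011
2	synthetic	gene	61000000	61150000	.	-	.	ID=SYNG0012;Name=SYNG0012
2	synthetic	gene	80000000	80090000	.	+	.	ID=SYNG0013;Name=SYNG0013
2	synthetic	gene	95000000	95200000	.	-	.	ID=SYNG0014;Name=SYNG0014
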