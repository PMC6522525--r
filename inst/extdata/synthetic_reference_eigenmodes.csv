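frequency_hz,mode1,mode2,mode3,mode4,mode5
500,-0.000434,-2.2e-05,-5.6e-05,0.222851,0.122356
750,-0.001376,-7e-05,-0.000177,-0.085552,-0.282306
1000,-0.003099,-0.000158,-0.000398,-0.271635,-0.309531
1250,-0.005774,-0.000295,-0.000741,-0.324549,-0.122459
1500,-0.009513,-0.000485,-0.001221,-0.293077,0.099223
1750,-0.014358,-0.000732,-0.001843,-0.217778,0.270842
2000,-0.020277,-0.001034,-0.002603,-0.124877,0.368524
2250,-0.027166,-0.001383,-0.00349,-0.029851,0.396721
2500,-0.034861,-0.00175,-0.004515,0.058741,0.37021
2750,-0.043159,-0.002026,-0.005865,0.136436,0.305718
3000,-0.051835,-0.001873,-0.008323,0.200801,0.218764
3250,-0.060668,-0.000497,-0.013827,0.249887,0.123065
3500,-0.069459,0.003499,-0.025402,0.281413,0.030787
3750,-0.078037,0.01199,-0.045763,0.293046,-0.047537
4000,-0.086272,0.026816,-0.075116,0.2836,-0.103833
4250,-0.094068,0.04905,-0.109839,0.254293,-0.133694
4500,-0.101365,0.078379,-0.143293,0.209135,-0.137141
4750,-0.108134,0.112891,-0.16837,0.154221,-0.118404
5000,-0.114366,0.14939,-0.18017,0.096332,-0.084693
5250,-0.120071,0.184089,-0.177426,0.041557,-0.044418
5500,-0.125271,0.213406,-0.162275,-0.005622,-0.005414
5750,-0.129993,0.234634,-0.138929,-0.042659,0.026348
6000,-0.134273,0.2463,-0.112092,-0.068816,0.047396
6250,-0.138146,0.248212,-0.085757,-0.084767,0.056761
6500,-0.141647,0.241256,-0.062596,-0.092114,0.055521
6750,-0.14481,0.227053,-0.043834,-0.092911,0.046114
7000,-0.147669,0.207587,-0.029366,-0.089233,0.031612
7250,-0.150253,0.18488,-0.017856,-0.082807,0.015079
7500,-0.152591,0.160752,-0.006774,-0.07472,-0.000906
7750,-0.154707,0.136682,0.007438,-0.065298,-0.014517
8000,-0.156625,0.113743,0.028768,-0.05424,-0.024737
8250,-0.158365,0.092593,0.060388,-0.041061,-0.031221
8500,-0.159946,0.073506,0.103072,-0.025704,-0.034045
8750,-0.161385,0.056415,0.15401,-0.009017,-0.033473
9000,-0.162695,0.040967,0.206828,0.00718,-0.02985
9250,-0.16389,0.026586,0.253072,0.020569,-0.023666
9500,-0.164983,0.012551,0.284668,0.029135,-0.015703
9750,-0.165982,-0.001911,0.296291,0.031919,-0.007141
10000,-0.166898,-0.017511,0.286714,0.029376,0.000494
10250,-0.167738,-0.034786,0.258697,0.023192,0.005579
10500,-0.16851,-0.053997,0.217704,0.015691,0.006753
10750,-0.169221,-0.075056,0.17008,0.009081,0.003287
11000,-0.169876,-0.097506,0.121372,0.004813,-0.004666
11250,-0.17048,-0.120552,0.075231,0.003224,-0.016004
11500,-0.171039,-0.143151,0.033061,0.003516,-0.028821
11750,-0.171556,-0.164137,-0.005625,0.004044,-0.040704
12000,-0.172034,-0.182363,-0.042313,0.002822,-0.049141
12250,-0.172479,-0.19684,-0.078329,-0.001889,-0.051947
12500,-0.172891,-0.206844,-0.113827,-0.011067,-0.047613
12750,-0.173275,-0.211983,-0.147301,-0.024675,-0.035506
13000,-0.173633,-0.212217,-0.175864,-0.041734,-0.015874
13250,-0.173966,-0.207835,-0.196196,-0.060702,0.010319
13500,-0.174277,-0.199396,-0.205739,-0.079979,0.041655
13750,-0.174567,-0.187647,-0.203635,-0.098352,0.076546
14000,-0.174839,-0.173441,-0.191019,-0.115209,0.113445
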