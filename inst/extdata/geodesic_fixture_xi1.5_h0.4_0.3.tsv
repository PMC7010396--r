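s	x	y	theta	h1	h2	h3
0.00000000000e+00	0.00000000000e+00	 0.00000000000e+00	0.00000000000e+00	1.37477270849e+00	4.00000000000e-01	3.00000000000e-01
1.83673469388e-02	1.83668987635e-02	-1.11050548859e-04	1.21254832376e-02	1.37107938722e+00	4.05594934187e-01	3.09247576058e-01
3.67346938776e-02	3.67310617165e-02	-4.46859880221e-04	2.44641429454e-02	1.36720881632e+00	4.11360913481e-01	3.18625566182e-01
5.51020408163e-02	5.50896169374e-02	-1.01178699313e-03	3.70324404113e-02	1.36315292747e+00	4.17300369477e-01	3.28137925204e-01
7.34693877551e-02	7.34395281765e-02	-1.81069984804e-03	4.98474009016e-02	1.35890318732e+00	4.23415806928e-01	3.37788664620e-01
9.18367346939e-02	9.17775762517e-02	-2.84899211269e-03	6.29266659272e-02	1.35445056692e+00	4.29709804800e-01	3.47581854282e-01
1.10204081633e-01	1.10100339023e-01	-4.13260150424e-03	7.62885485261e-02	1.34978550849e+00	4.36185017360e-01	3.57521624117e-01
1.28571428571e-01	1.28404169790e-01	-5.66802971875e-03	8.99520918570e-02	1.34489788903e+00	4.42844175296e-01	3.67612165866e-01
1.46938775510e-01	1.46685173937e-01	-7.46236392657e-03	1.03937131426e-01	1.33977698069e+00	4.49690086871e-01	3.77857734853e-01
1.65306122449e-01	1.64939183644e-01	-9.52329979521e-03	1.18264361281e-01	1.33441140726e+00	4.56725639101e-01	3.88262651778e-01
1.83673469388e-01	1.83161730464e-01	-1.18591659790e-02	1.32955404556e-01	1.32878909648e+00	4.63953798979e-01	3.98831304543e-01
2.02040816327e-01	2.01348015533e-01	-1.44789499870e-02	1.48032888737e-01	1.32289722759e+00	4.71377614720e-01	4.09568150097e-01
2.20408163265e-01	2.19492877178e-01	-1.73923253033e-02	1.63520526112e-01	1.31672217348e+00	4.79000217053e-01	4.20477716319e-01
2.38775510204e-01	2.37590755658e-01	-2.06096795912e-02	1.79443199836e-01	1.31024943684e+00	4.86824820537e-01	4.31564603928e-01
2.57142857143e-01	2.55635654746e-01	-2.41421437532e-02	1.95827056150e-01	1.30346357938e+00	4.94854724918e-01	4.42833488421e-01
2.75510204082e-01	2.73621099837e-01	-2.80016215525e-02	2.12699603282e-01	1.29634814323e+00	5.03093316519e-01	4.54289122044e-01
2.93877551020e-01	2.91540092241e-01	-3.22008194145e-02	2.30089817668e-01	1.28888556349e+00	5.11544069671e-01	4.65936335801e-01
3.12244897959e-01	3.09385059281e-01	-3.67532759243e-02	2.48028258153e-01	1.28105707036e+00	5.20210548176e-01	4.77780041486e-01
3.30612244898e-01	3.27147799806e-01	-4.16733904071e-02	2.66547188947e-01	1.27284257969e+00	5.29096406810e-01	4.89825233756e-01
3.48979591837e-01	3.44819424661e-01	-4.69764498303e-02	2.85680712203e-01	1.26422056974e+00	5.38205392865e-01	5.02076992239e-01
3.67346938776e-01	3.62390291659e-01	-5.26786530759e-02	3.05464911196e-01	1.25516794222e+00	5.47541347729e-01	5.14540483675e-01
3.85714285714e-01	3.79849934532e-01	-5.87971314174e-02	3.25938005289e-01	1.24565986491e+00	5.57108208505e-01	5.27220964094e-01
4.04081632653e-01	3.97186985331e-01	-6.53499637684e-02	3.47140518041e-01	1.23566959261e+00	5.66910009675e-01	5.40123781033e-01
4.22448979592e-01	4.14389089675e-01	-7.23561849598e-02	3.69115460140e-01	1.22516826281e+00	5.76950884796e-01	5.53254375793e-01
4.40816326531e-01	4.31442814251e-01	-7.98357849342e-02	3.91908529208e-01	1.21412466119e+00	5.87235068247e-01	5.66618285730e-01
4.59183673469e-01	4.48333545885e-01	-8.78096963152e-02	4.15568329050e-01	1.20250495129e+00	5.97766897012e-01	5.80221146594e-01
4.77551020408e-01	4.65045381519e-01	-9.62997673035e-02	4.40146611658e-01	1.19027236141e+00	6.08550812513e-01	5.94068694903e-01
4.95918367347e-01	4.81561008344e-01	-1.05328716273e-01	4.65698546236e-01	1.17738681960e+00	6.19591362480e-01	6.08166770364e-01
5.14285714286e-01	4.97861573351e-01	-1.14920063770e-01	4.92283020916e-01	1.16380452603e+00	6.30893202867e-01	6.22521318334e-01
5.32653061224e-01	5.13926541474e-01	-1.25098036852e-01	5.19962984728e-01	1.14947744834e+00	6.42461099821e-01	6.37138392328e-01
5.51020408163e-01	5.29733541503e-01	-1.35887439870e-01	5.48805840096e-01	1.13435272232e+00	6.54299931686e-01	6.52024156574e-01
5.69387755102e-01	5.45258198842e-01	-1.47313484814e-01	5.78883899909e-01	1.11837193453e+00	6.66414691066e-01	6.67184888607e-01
5.87755102041e-01	5.60473954117e-01	-1.59401573327e-01	6.10274928639e-01	1.10147025670e+00	6.78810486925e-01	6.82626981923e-01
6.06122448980e-01	5.75351866493e-01	-1.72177021361e-01	6.43062794671e-01	1.08357539195e+00	6.91492546745e-01	6.98356948669e-01
6.24489795918e-01	5.89860400313e-01	-1.85664716252e-01	6.77338272160e-01	1.06460627934e+00	7.04466218730e-01	7.14381422396e-01
6.42857142857e-01	6.03965193274e-01	-1.99888694730e-01	7.13200046920e-01	1.04447148412e+00	7.17736974060e-01	7.30707160849e-01
6.61224489796e-01	6.17628803746e-01	-2.14871629121e-01	7.50756004672e-01	1.02306717381e+00	7.31310409201e-01	7.47341048824e-01
6.79591836735e-01	6.30810433745e-01	-2.30634207638e-01	7.90124915559e-01	1.00027453959e+00	7.45192248261e-01	7.64290101065e-01
6.97959183673e-01	6.43465622416e-01	-2.47194393264e-01	8.31438682660e-01	9.75956462621e-01	7.59388345408e-01	7.81561465226e-01
7.16326530612e-01	6.55545902119e-01	-2.64566544125e-01	8.74845405556e-01	9.49953132301e-01	7.73904687336e-01	7.99162424887e-01
7.34693877551e-01	6.66998404749e-01	-2.82760376148e-01	9.20513641708e-01	9.22076177803e-01	7.88747395791e-01	8.17100402619e-01
7.53061224490e-01	6.77765398730e-01	-3.01779745651e-01	9.68638462792e-01	8.92100638307e-01	8.03922730154e-01	8.35382963121e-01
7.71428571429e-01	6.87783725160e-01	-3.21621224063e-01	1.01945026372e+00	8.59753700001e-01	8.19437090077e-01	8.54017816407e-01
7.89795918367e-01	6.96984081614e-01	-3.42272426843e-01	1.07322791344e+00	8.24698433175e-01	8.35297018183e-01	8.73012821058e-01
8.08163265306e-01	7.05290067559e-01	-3.63710039230e-01	1.13031899531e+00	7.86509487779e-01	8.51509202830e-01	8.92375987535e-01
8.26530612245e-01	7.12616843440e-01	-3.85897442908e-01	1.19117213668e+00	7.44635230796e-01	8.68080480923e-01	9.12115481559e-01
8.44897959184e-01	7.18869138430e-01	-4.08781769385e-01	1.25639111601e+00	6.98335663044e-01	8.85017840805e-01	9.32239627552e-01
8.63265306122e-01	7.23938105196e-01	-4.32290039683e-01	1.32683107885e+00	6.46573800449e-01	9.02328425199e-01	9.52756912151e-01
8.81632653061e-01	7.27695995443e-01	-4.56323672170e-01	1.40378417065e+00	5.87808750751e-01	9.20019534223e-01	9.73675987785e-01
9.00000000000e-01	7.29986314965e-01	-4.80749686269e-01	1.48938123160e+00	5.19552372099e-01	9.38098628467e-01	9.95005676323e-01
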