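"time_s","value"
0,-0.00026837832324455
0.1,-0.00535108492290007
0.2,-0.0181767289596465
0.3,-0.0368564148535957
0.4,-0.0597541359888598
0.5,-0.0854714380862731
0.6,-0.112830013503144
0.7,-0.140853019460363
0.8,-0.168745781557533
0.9,-0.195876424403948
1,-0.221756863926543
1.1,-0.246024500776783
1.2,-0.268424870873028
1.3,-0.288795436929962
1.4,-0.307050643156934
1.5,-0.323168303377201
1.6,-0.337177349799292
1.7,-0.34914693470293
1.8,-0.359176849525689
1.9,-0.367389204410232
2,-0.373921295384301
2.1,-0.378919575228512
2.2,-0.382534637023088
2.3,-0.384917115692798
2.4,-0.386214411987829
2.5,-0.386568144705554
2.6,-0.3861122400929
2.7,-0.384971571848151
2.8,-0.38326107059737
2.9,-0.381085227839661
3,-0.378537925871323
3.1,-0.375702531890705
3.2,-0.372652201172753
3.3,-0.369450340740863
3.4,-0.366151191241756
3.5,-0.362800490662908
3.6,-0.359436189062163
3.7,-0.356089188566686
3.8,-0.352784087522001
3.9,-0.349539911824519
4,-0.346370820157203
4.1,-0.343286773081623
4.2,-0.34029415874155
4.3,-0.337396370329249
4.4,-0.334594332485494
4.5,-0.331886975479711
4.6,-0.329271657380523
4.7,-0.326744535512268
4.8,-0.324300889332249
4.9,-0.321935397487806
5,-0.319642372251415
5.1,-0.317415954813529
5.2,-0.31525027506246
5.3,-0.313139579521405
5.4,-0.311078331065795
5.5,-0.309061283928066
5.6,-0.307083537328186
5.7,-0.305140570861028
5.8,-0.303228264538169
5.9,-0.301342906132305
6,-0.299481188215758
6.1,-0.297640197027547
6.2,-0.295817395051862
6.3,-0.294010598948892
6.4,-0.292217954250041
6.5,-0.290437908016077
6.6,-0.28866918046013
6.7,-0.28691073635864
6.8,-0.285161756912589
6.9,-0.283421612578545
7,-0.28168983726364
7.1,-0.279966104169887
7.2,-0.278250203480107
7.3,-0.27654202199924
7.4,-0.274841524799515
7.5,-0.273148738864817
7.6,-0.271463738687153
7.7,-0.26978663373527
7.8,-0.26811755769097
7.9,-0.266456659331285
8,-0.264804094923523
8.1,-0.263160021994066
8.2,-0.261524594329998
8.3,-0.259897958074207
8.4,-0.258280248778907
8.5,-0.256671589288857
8.6,-0.255072088333462
8.7,-0.253481839715803
8.8,-0.251900921996218
8.9,-0.250329398577901
9,-0.248767318111836
9.1,-0.247214715148106
9.2,-0.245671610969904
9.3,-0.24413801455541
9.4,-0.242613923620951
9.5,-0.241099325706459
9.6,-0.239594199271131
9.7,-0.238098514773453
9.8,-0.236612235715272
9.9,-0.235135319634441
10,-0.233667719034814
10.1,-0.23220938224596
10.2,-0.230760254208039
10.3,-0.2293202771798
10.4,-0.227889391369766
10.5,-0.22646753549229
10.6,-0.225054647251491
10.7,-0.223650663757007
10.8,-0.222255521876217
10.9,-0.220869158528005
11,-0.219491510923403
11.1,-0.218122516758519
11.2,-0.216762114365114
11.3,-0.215410242824021
11.4,-0.214066842046382
11.5,-0.212731852827345
11.6,-0.211405216876567
11.7,-0.210086876829465
11.8,-0.208776776242803
11.9,-0.207474859577812
12,-0.20618107217368
12.1,-0.204895360213868
12.2,-0.203617670687394
12.3,-0.202347951346888
12.4,-0.201086150664938
12.5,-0.199832217789978
12.6,-0.198586102502722
12.7,-0.197347755173945
12.8,-0.196117126724211
12.9,-0.194894168585998
13,-0.193678832668512
13.1,-0.192471071325378
13.2,-0.191270837325299
13.3,-0.19007808382567
13.4,-0.188892764349103
13.5,-0.187714832762737
13.6,-0.186544243260194
13.7,-0.185380950345998
13.8,-0.184224908822266
13.9,-0.183076073777465
14,-0.181934400577025
14.1,-0.180799844855607
14.2,-0.179672362510827
14.3,-0.17855190969823
14.4,-0.177438442827359
14.5,-0.176331918558724
14.6,-0.175232293801541
14.7,-0.174139525712088
14.8,-0.173053571692564
14.9,-0.17197438939033
15,-0.17090193669745
15.1,-0.169836171750433
15.2,-0.168777052930118
15.3,-0.167724538861648
15.4,-0.166678588414458
15.5,-0.165639160702269
15.6,-0.164606215083038
15.7,-0.163579711158845
15.8,-0.1625596087757
15.9,-0.161545868023254
16,-0.16053844923442
16.1,-0.159537312984879
16.2,-0.158542420092488
16.3,-0.157553731616587
16.4,-0.156571208857207
16.5,-0.155594813354187
16.6,-0.1546245068862
16.7,-0.153660251469714
16.8,-0.152702009357866
16.9,-0.151749743039291
17,-0.150803415236882
17.1,-0.149862988906511
17.2,-0.148928427235712
17.3,-0.147999693642325
17.4,-0.147076751773116
17.5,-0.146159565502385
17.6,-0.145248098930545
17.7,-0.144342316382701
17.8,-0.143442182407218
17.9,-0.142547661774293
18,-0.141658719474519
18.1,-0.140775320717456
18.2,-0.139897430930212
18.3,-0.139025015756027
18.4,-0.138158041052864
18.5,-0.137296472892019
18.6,-0.13644027755673
18.7,-0.135589421540808
18.8,-0.134743871547275
18.9,-0.133903594487015
19,-0.13306855747744
19.1,-0.132238727841163
19.2,-0.13141407310469
19.3,-0.130594560997119
19.4,-0.129780159448854
19.5,-0.128970836590326
19.6,-0.128166560750733
19.7,-0.127367300456783
19.8,-0.126573024431452
19.9,-0.12578370159275
20,-0.124999301052499
20.1,-0.124219792115118
20.2,-0.123445144276419
20.3,-0.122675327222409
20.4,-0.121910310828107
20.5,-0.121150065156362
20.6,-0.120394560456682
20.7,-0.119643767164072
20.8,-0.11889765589788
20.9,-0.118156197460646
21,-0.117419362836964
21.1,-0.116687123192349
21.2,-0.11595944987211
21.3,-0.115236314400231
21.4,-0.11451768847826
21.5,-0.113803543984202
21.6,-0.113093852971424
21.7,-0.112388587667558
21.8,-0.111687720473421
21.9,-0.110991223961934
22,-0.110299070877049
22.1,-0.109611234132689
22.2,-0.10892768681168
22.3,-0.10824840216471
22.4,-0.107573353609272
22.5,-0.106902514728631
22.6,-0.106235859270791
22.7,-0.105573361147465
22.8,-0.104914994433054
22.9,-0.104260733363637
23,-0.10361055233596
23.1,-0.102964425906433
23.2,-0.10232232879014
23.3,-0.101684235859841
23.4,-0.101050122144996
23.5,-0.100419962830785
23.6,-0.0997937332571364
23.7,-0.0991714089177627
23.8,-0.0985529654592014
23.9,-0.0979383786798619
24,-0.0973276245290777
24.1,-0.0967206791061662
24.2,-0.0961175186594922
24.3,-0.0955181195855391
24.4,-0.0949224584279849
24.5,-0.0943305118767841
24.6,-0.0937422567672555
24.7,-0.0931576700791758
24.8,-0.0925767289358784
24.9,-0.0919994106033582
25,-0.0914256924893821
25.1,-0.0908555521426046
25.2,-0.0902889672516893
25.3,-0.0897259156444358
25.4,-0.0891663752869118
25.5,-0.088610324282591
25.6,-0.0880577408714963
25.7,-0.087508603429348
25.8,-0.0869628904667176
25.9,-0.086420580628187
26,-0.0858816526915129
26.1,-0.0853460855667959
26.2,-0.0848138582956554
26.3,-0.0842849500504096
26.4,-0.0837593401332601
26.5,-0.0832370079754824
26.6,-0.0827179331366205
26.7,-0.0822020953036872
26.8,-0.0816894742903693
26.9,-0.0811800500362376
27,-0.0806738026059617
27.1,-0.0801707121885302
27.2,-0.0796707590964751
27.3,-0.0791739237651016
27.4,-0.0786801867517224
27.5,-0.0781895287348967
27.6,-0.0777019305136745
27.7,-0.0772173730068448
27.8,-0.076735837252189
27.9,-0.0762573044057391
28,-0.0757817557410399
28.1,-0.0753091726484165
28.2,-0.0748395366342459
28.3,-0.0743728293202331
28.4,-0.0739090324426924
28.5,-0.0734481278518321
28.6,-0.0729900975110448
28.7,-0.072534923496201
28.8,-0.0720825879949484
28.9,-0.071633073306014
29,-0.0711863618385121
29.1,-0.0707424361112555
29.2,-0.0703012787520716
29.3,-0.0698628724971224
29.4,-0.0694272001902293
29.5,-0.0689942447822013
29.6,-0.0685639893301679
29.7,-0.0681364169969161
29.8,-0.0677115110502319
29.9,-0.0672892548622448
30,-0.0668696319087775
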