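# q intensity uncertainty
# synthetic reduced curve from the GLW simulator
# truth: sigma_k=0.12 ln_gamma=2.5 alpha=0.3 d=40A scale=1 bkg=0 noise=5%
# columns: Q [1/Angstrom], intensity [arb], uncertainty
0.02 11.14738591 0.5743419948
0.02322147651 10.82202069 0.5403824782
0.02644295302 9.397555718 0.5084309094
0.02966442953 8.915520739 0.4783685632
0.03288590604 9.532093482 0.4500837341
0.03610738255 8.07384014 0.4234713217
0.03932885906 8.498273619 0.3985383035
0.04255033557 7.846897137 0.3804571352
0.04577181208 7.247319317 0.3631962862
0.04899328859 6.586223573 0.3467185396
0.0522147651 6.345565579 0.3309883671
0.05543624161 6.209367705 0.3159718523
0.05865771812 5.568726729 0.3016366173
0.06187919463 5.575836069 0.2824003897
0.06510067114 4.975728144 0.263963588
0.06832214765 4.937650479 0.246730452
0.07154362416 4.561026213 0.2306223992
0.07476510067 4.502692907 0.2155659772
0.07798657718 3.910535721 0.2014925293
0.08120805369 3.843695265 0.1986992998
0.0844295302 3.827425615 0.1981327349
0.08765100671 3.948222641 0.1975677855
0.09087248322 3.852893827 0.1970044469
0.09409395973 3.998111645 0.1964427146
0.09731543624 3.931984524 0.1958825841
0.1005369128 4.21526178 0.2106876754
0.1037583893 4.615112842 0.2329406264
0.1069798658 4.953677367 0.2575439467
0.1102013423 5.631972649 0.2847458835
0.1134228188 5.986763834 0.3148209041
0.1166442953 6.57707844 0.3480724654
0.1198657718 7.306091142 0.3832834286
0.1230872483 8.707567608 0.4210902768
0.1263087248 8.522735288 0.4626263699
0.1295302013 9.723036632 0.5082595584
0.1327516779 11.43852029 0.5583939774
0.1359731544 12.15533408 0.6134736254
0.1391946309 13.86525585 0.64353209
0.1424161074 12.58941487 0.6493198026
0.1456375839 12.87535537 0.6551595679
0.1488590604 12.13921495 0.6610518542
0.1520805369 13.35353704 0.6669971337
0.1553020134 14.06005681 0.672995883
0.1585234899 12.29110561 0.6425965783
0.1617449664 11.97573869 0.5732747512
0.164966443 10.05275597 0.5114312019
0.1681879195 8.127444725 0.4562591912
0.171409396 8.498998186 0.4070390088
0.1746308725 7.525424717 0.3631285855
0.177852349 6.415529813 0.3172886526
0.1810738255 5.548328925 0.2668765496
0.184295302 4.437854824 0.2244741252
0.1875167785 3.621634939 0.1888087693
0.190738255 3.2555642 0.1588100692
0.1939597315 2.692818221 0.1335776838
0.1971812081 2.305669428 0.1122382981
0.2004026846 1.865838124 0.0940283601
0.2036241611 1.610022344 0.07877286679
0.2068456376 1.418037841 0.06599247862
0.2100671141 1.10903878 0.05528562576
0.2132885906 0.8869950238 0.04631589054
0.2165100671 0.8808165793 0.03942832057
0.2197315436 0.7244028212 0.03644097877
0.2229530201 0.6079166024 0.0336799771
0.2261744966 0.6393324325 0.03112816658
0.2293959732 0.6241158599 0.02876969754
0.2326174497 0.5107666415 0.02658992121
0.2358389262 0.4668315712 0.02466779391
0.2390604027 0.467180439 0.02409124539
0.2422818792 0.4883131374 0.02352817226
0.2455033557 0.4699852821 0.02297825957
0.2487248322 0.4460539947 0.02244119973
0.2519463087 0.4216092883 0.02191669233
0.2551677852 0.4329748741 0.02140444399
0.2583892617 0.456139042 0.02159804278
0.2616107383 0.4396766336 0.02181306463
0.2648322148 0.4254307365 0.02203022715
0.2680536913 0.4550689589 0.02224955167
0.2712751678 0.4254322893 0.02247105969
0.2744966443 0.463008889 0.02269477296
0.2777181208 0.4544286759 0.02279526045
0.2809395973 0.4647932406 0.02287875393
0.2841610738 0.4453430696 0.02296255322
0.2873825503 0.4400163938 0.02304665945
0.2906040268 0.5149349189 0.02313107375
0.2938255034 0.4503115556 0.02321579723
0.2970469799 0.4241734987 0.02268048182
0.3002684564 0.4509881453 0.02199250084
0.3034899329 0.4083100913 0.02132538881
0.3067114094 0.3824277566 0.0206785127
0.3099328859 0.4251333815 0.02005125869
0.3131543624 0.3688758119 0.01944303155
0.3163758389 0.3892114998 0.01858852238
0.3195973154 0.3435689456 0.01765799849
0.3228187919 0.344087801 0.01677405574
0.3260402685 0.3130689357 0.01593436233
0.329261745 0.3228134042 0.01513670318
0.3324832215 0.2711852681 0.0143789741
0.335704698 0.2921142276 0.01364184037
0.3389261745 0.2508375208 0.0129312214
0.342147651 0.2397385817 0.01225761938
0.3453691275 0.2352129858 0.01161910605
0.348590604 0.2268499325 0.01101385361
0.3518120805 0.2075493486 0.01044012946
0.355033557 0.1776145694 0.009905857684
0.3582550336 0.1936713118 0.009408084832
0.3614765101 0.1830793764 0.008935325242
0.3646979866 0.1611841395 0.008486321989
0.3679194631 0.171430881 0.008059881308
0.3711409396 0.1617008165 0.007654869422
0.3743624161 0.152598666 0.007321520206
0.3775838926 0.152987923 0.007076022624
0.3808053691 0.139836614 0.006838756811
0.3840268456 0.1169944419 0.006609446747
0.3872483221 0.1272508298 0.00638782567
0.3904697987 0.120243506 0.00617363576
0.3936912752 0.1173942961 0.005994881862
0.3969127517 0.1194621687 0.005883422193
0.4001342282 0.1152995418 0.005774034834
0.4033557047 0.113929333 0.005666681257
0.4065771812 0.1249213554 0.005561323648
0.4097986577 0.1056654871 0.005457924897
0.4130201342 0.1136923585 0.005359967586
0.4162416107 0.1092836679 0.005276558663
0.4194630872 0.1028364664 0.005194447704
0.4226845638 0.1094888284 0.005113614512
0.4259060403 0.1071686907 0.005034039202
0.4291275168 0.1020154728 0.0049557022
0.4323489933 0.1037844232 0.004877321164
0.4355704698 0.09163115139 0.004790894779
0.4387919463 0.09346773304 0.004705999875
0.4420134228 0.0869272467 0.004622609313
0.4452348993 0.09230967988 0.004540696437
0.4484563758 0.08437679276 0.00446023506
0.4516778523 0.08533579614 0.004380085162
0.4548993289 0.08476806767 0.004255030483
0.4581208054 0.08122723021 0.004133546207
0.4613422819 0.07124231905 0.004015530398
0.4645637584 0.07689994937 0.003900884028
0.4677852349 0.07685355814 0.003789510896
0.4710067114 0.06789774557 0.00368131755
0.4742281879 0.07408158413 0.003605964565
0.4774496644 0.06525080892 0.003534427674
0.4806711409 0.06827302748 0.003464309967
0.4838926174 0.06753409065 0.003395583289
0.487114094 0.06742494601 0.003328220045
0.4903355705 0.06651295169 0.003262193185
0.493557047 0.0701609611 0.003186883254
0.4967785235 0.06121778854 0.003111240021
0.5 0.06189799003 0.003037392241
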