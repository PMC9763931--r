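bed,component,group,age_weeks,mean,se
peripheral,ach_dilation,LZR,7,119.2,1.1
peripheral,ach_dilation,LZR,10,125.0,1.1
peripheral,ach_dilation,LZR,13,129.3,1.2
peripheral,ach_dilation,LZR,17,136.5,2.0
peripheral,ach_dilation,LZR,20,139.9,1.6
peripheral,ach_dilation,OZR,7,115.3,1.9
peripheral,ach_dilation,OZR,10,118.4,3.2
peripheral,ach_dilation,OZR,13,120.5,2.8
peripheral,ach_dilation,OZR,17,122.6,2.9
peripheral,ach_dilation,OZR,20,119.3,3.3
peripheral,ach_dilation,OZR_EXERCISE,7,117.6,2.6
peripheral,ach_dilation,OZR_EXERCISE,10,127.3,2.2
peripheral,ach_dilation,OZR_EXERCISE,13,131.7,2.3
peripheral,ach_dilation,OZR_EXERCISE,17,129.6,3.4
peripheral,ach_dilation,OZR_CAPTOPRIL,7,118.3,2.7
peripheral,ach_dilation,OZR_CAPTOPRIL,10,117.0,2.1
peripheral,ach_dilation,OZR_CAPTOPRIL,13,124.8,3.9
peripheral,ach_dilation,OZR_CAPTOPRIL,17,124.3,1.9
peripheral,snp_dilation,LZR,7,128.8,0.9
peripheral,snp_dilation,LZR,10,130.6,1.0
peripheral,snp_dilation,LZR,13,132.9,1.2
peripheral,snp_dilation,LZR,17,140.3,2.2
peripheral,snp_dilation,LZR,20,140.7,1.4
peripheral,snp_dilation,OZR,7,127.7,2.2
peripheral,snp_dilation,OZR,10,131.5,3.3
peripheral,snp_dilation,OZR,13,134.1,2.6
peripheral,snp_dilation,OZR,17,139.8,3.7
peripheral,snp_dilation,OZR,20,135.6,4.8
peripheral,snp_dilation,OZR_EXERCISE,7,127.0,2.7
peripheral,snp_dilation,OZR_EXERCISE,10,132.0,1.8
peripheral,snp_dilation,OZR_EXERCISE,13,135.7,2.3
peripheral,snp_dilation,OZR_EXERCISE,17,134.4,3.8
peripheral,snp_dilation,OZR_CAPTOPRIL,7,130.8,3.2
peripheral,snp_dilation,OZR_CAPTOPRIL,10,134.3,1.5
peripheral,snp_dilation,OZR_CAPTOPRIL,13,138.5,3.4
peripheral,snp_dilation,OZR_CAPTOPRIL,17,134.0,2.6
peripheral,mvd,LZR,7,809.9,13.9
peripheral,mvd,LZR,10,810.4,13.1
peripheral,mvd,LZR,13,811.8,11.9
peripheral,mvd,LZR,17,863.1,4.6
peripheral,mvd,LZR,20,823.0,9.1
peripheral,mvd,OZR,7,805.4,25.2
peripheral,mvd,OZR,10,782.4,26.1
peripheral,mvd,OZR,13,706.9,16.9
peripheral,mvd,OZR,17,656.3,20.5
peripheral,mvd,OZR,20,635.9,11.6
peripheral,mvd,OZR_EXERCISE,7,881.4,10.8
peripheral,mvd,OZR_EXERCISE,10,874.6,14.6
peripheral,mvd,OZR_EXERCISE,13,832.3,21.5
peripheral,mvd,OZR_EXERCISE,17,869.4,17.3
peripheral,mvd,OZR_CAPTOPRIL,7,833.3,12.3
peripheral,mvd,OZR_CAPTOPRIL,10,813.3,5.5
peripheral,mvd,OZR_CAPTOPRIL,13,764.0,8.0
peripheral,mvd,OZR_CAPTOPRIL,17,730.5,16.6
peripheral,hypoxic_dilation,LZR,7,120.8,1.1
peripheral,hypoxic_dilation,LZR,10,125.0,1.0
peripheral,hypoxic_dilation,LZR,13,128.9,1.2
peripheral,hypoxic_dilation,LZR,17,135.3,1.8
peripheral,hypoxic_dilation,LZR,20,135.8,2.0
peripheral,hypoxic_dilation,OZR,7,117.0,2.2
peripheral,hypoxic_dilation,OZR,10,118.1,3.1
peripheral,hypoxic_dilation,OZR,13,119.6,3.1
peripheral,hypoxic_dilation,OZR,17,121.6,4.1
peripheral,hypoxic_dilation,OZR,20,118.4,2.1
peripheral,hypoxic_dilation,OZR_EXERCISE,7,121.1,2.3
peripheral,hypoxic_dilation,OZR_EXERCISE,10,126.6,2.3
peripheral,hypoxic_dilation,OZR_EXERCISE,13,129.6,2.5
peripheral,hypoxic_dilation,OZR_EXERCISE,17,125.6,4.8
peripheral,hypoxic_dilation,OZR_CAPTOPRIL,7,119.5,3.0
peripheral,hypoxic_dilation,OZR_CAPTOPRIL,10,119.5,2.3
peripheral,hypoxic_dilation,OZR_CAPTOPRIL,13,126.8,3.2
peripheral,hypoxic_dilation,OZR_CAPTOPRIL,17,123.0,4.0
peripheral,stiffness_beta,LZR,7,2.6,0.1
peripheral,stiffness_beta,LZR,10,2.6,0.1
peripheral,stiffness_beta,LZR,13,2.8,0.1
peripheral,stiffness_beta,LZR,17,3.1,0.1
peripheral,stiffness_beta,LZR,20,3.2,0.1
peripheral,stiffness_beta,OZR,7,2.4,0.3
peripheral,stiffness_beta,OZR,10,3.4,0.5
peripheral,stiffness_beta,OZR,13,4.1,0.6
peripheral,stiffness_beta,OZR,17,6.2,0.4
peripheral,stiffness_beta,OZR,20,5.7,0.7
peripheral,stiffness_beta,OZR_EXERCISE,7,3.7,0.3
peripheral,stiffness_beta,OZR_EXERCISE,10,3.5,0.3
peripheral,stiffness_beta,OZR_EXERCISE,13,3.8,0.4
peripheral,stiffness_beta,OZR_EXERCISE,17,4.0,0.3
peripheral,stiffness_beta,OZR_CAPTOPRIL,7,3.2,0.2
peripheral,stiffness_beta,OZR_CAPTOPRIL,10,3.5,0.3
peripheral,stiffness_beta,OZR_CAPTOPRIL,13,4.2,0.2
peripheral,stiffness_beta,OZR_CAPTOPRIL,17,4.8,0.3
cerebral,ach_dilation,LZR,7,135.2,1.3
cerebral,ach_dilation,LZR,10,144.1,0.9
cerebral,ach_dilation,LZR,13,151.8,0.8
cerebral,ach_dilation,LZR,17,155.0,1.4
cerebral,ach_dilation,LZR,20,163.0,1.1
cerebral,ach_dilation,OZR,7,122.4,1.3
cerebral,ach_dilation,OZR,10,128.4,1.0
cerebral,ach_dilation,OZR,13,125.1,0.8
cerebral,ach_dilation,OZR,17,122.9,1.7
cerebral,ach_dilation,OZR,20,119.8,2.5
cerebral,ach_dilation,OZR_CAPTOPRIL,7,137.5,0.7
cerebral,ach_dilation,OZR_CAPTOPRIL,13,139.0,0.7
cerebral,ach_dilation,OZR_CAPTOPRIL,17,132.5,2.4
cerebral,snp_dilation,LZR,7,142.7,1.2
cerebral,snp_dilation,LZR,10,151.4,0.6
cerebral,snp_dilation,LZR,13,159.1,1.2
cerebral,snp_dilation,LZR,17,158.6,1.1
cerebral,snp_dilation,LZR,20,163.4,1.1
cerebral,snp_dilation,OZR,7,131.1,1.5
cerebral,snp_dilation,OZR,10,135.3,1.5
cerebral,snp_dilation,OZR,13,142.1,1.3
cerebral,snp_dilation,OZR,17,139.8,1.5
cerebral,snp_dilation,OZR,20,138.5,2.1
cerebral,mvd,LZR,7,290.0,1.9
cerebral,mvd,LZR,10,293.0,2.1
cerebral,mvd,LZR,13,303.8,1.2
cerebral,mvd,LZR,17,313.6,1.4
cerebral,mvd,LZR,20,319.6,1.0
cerebral,mvd,OZR,7,274.0,3.2
cerebral,mvd,OZR,10,270.1,2.6
cerebral,mvd,OZR,13,255.8,2.6
cerebral,mvd,OZR,17,249.1,2.1
cerebral,mvd,OZR,20,242.0,1.9
cerebral,mvd,OZR_CAPTOPRIL,7,337.3,2.7
cerebral,mvd,OZR_CAPTOPRIL,13,332.0,1.7
cerebral,mvd,OZR_CAPTOPRIL,17,310.3,2.2
cerebral,hypoxic_dilation,LZR,7,132.1,1.2
cerebral,hypoxic_dilation,LZR,10,140.2,0.7
cerebral,hypoxic_dilation,LZR,13,149.5,0.9
cerebral,hypoxic_dilation,LZR,17,152.6,1.5
cerebral,hypoxic_dilation,LZR,20,159.8,0.9
cerebral,hypoxic_dilation,OZR,7,122.6,1.6
cerebral,hypoxic_dilation,OZR,10,129.1,1.0
cerebral,hypoxic_dilation,OZR,13,127.1,0.8
cerebral,hypoxic_dilation,OZR,17,123.5,1.1
cerebral,hypoxic_dilation,OZR,20,120.6,2.4
cerebral,stiffness_beta,LZR,7,1.6,0.1
cerebral,stiffness_beta,LZR,10,1.7,0.1
cerebral,stiffness_beta,LZR,13,1.8,0.1
cerebral,stiffness_beta,LZR,17,2.0,0.1
cerebral,stiffness_beta,LZR,20,2.2,0.1
cerebral,stiffness_beta,OZR,7,1.8,0.1
cerebral,stiffness_beta,OZR,10,2.1,0.1
cerebral,stiffness_beta,OZR,13,2.8,0.2
cerebral,stiffness_beta,OZR,17,4.0,0.2
cerebral,stiffness_beta,OZR,20,5.4,0.1
cerebral,stiffness_beta,OZR_CAPTOPRIL,7,2.5,0.1
cerebral,stiffness_beta,OZR_CAPTOPRIL,13,3.3,0.1
cerebral,stiffness_beta,OZR_CAPTOPRIL,17,4.7,0.1
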