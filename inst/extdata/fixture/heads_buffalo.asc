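ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.264881 0.370021 0.0438996 3.06303 0.0173254 0.530711 0.400371 0.124202 0.584726 1.68061 0.240275 0.299527 0.326254 0.420985 5.67847 1.54409
0.341835 1.19049 0.294327 0.736697 0.110906 0.0933868 0.073237 0.0594163 0.166105 0.0403747 0.473137 0.110911 0.430792 10.3338 0.772955 3.06087
0.0328957 0.0577058  1.5723 0.107202 3.24037 0.72176 2.28584 0.76859 0.305344 1.34167 1.29186 0.621591 0.150878 2.83199 0.606567 0.172859
0.516236 0.492324 2.48513 0.732043 0.0732202 0.445666 1.04588 0.233823 1.59475 0.0800401 1.61081 6.78981 1.44455 1.74902 0.442321 11.5362
0.965416 0.609499 0.0691783 1.27468 0.420731 0.992927 1.34297 1.63377 0.287517 6.33052 3.64459 1.56995 0.350038 0.0481411 0.10294 4.34575
1.21595 1.56245 0.661689 0.112156 0.831594 0.111538 0.52673 0.0633666 1.57078 2.39111 12.7619 4.78456 1.97142 0.396663 0.248967 0.390983
1.20227  0.3442 0.313539 0.970658 0.356834 1.44986 0.025499 0.740891 0.514713 0.16773  2.9818 2.76549 0.279707 1.21717 1.42419 5.59542
0.755278 1.25786 0.0470233 0.0612755 0.473337 16.7138 0.0454864 0.0401905 0.492149 0.304237 0.060575 1.00614 0.812564 1.50992 6.37071 4.16767
0.489041 7.62465  1.2002 0.58078 0.0918984 20.7586 11.3718 0.18211 1.02383 2.76983 0.607541 5.37417 0.304313 0.177616 0.128237 1.43943
0.624722 1.41939 13.5145 2.34103 0.726122 5.69491 1.04925 0.533664 0.295976 7.31883 0.753729 1.42204 0.622277 1.29276 1.04253 1.34936
0.0231626 0.0867371 0.00362234 0.516899 0.081548 0.250821 0.334336 0.217009 3.62384 2.20642 0.577479 12.3465 0.925163 0.000225882 0.104407 0.0713604
2.01336 0.246018 3.40241 0.371104 0.102304 0.841784 0.251982 2.02623 0.104127 0.798391 0.58299 0.507741 0.0459571 0.636169 0.0439637 0.188092
0.205845 0.0863043 0.113724 0.341152 5.87878 0.240806 1.31944 18.7074 2.09488 0.391756 0.434202 1.67447 0.569776 1.41976 0.609687 0.860408
2.29002  1.7189 0.364841 1.65586 1.46248 1.76468 3.21988 0.795761 4.53231 0.0179442 0.069696 0.124625 0.0515444 0.485625 0.00438111 0.0490852
0.190004 14.5676 0.322566 4.28585 0.920649 0.360551 0.00912832 0.789931 7.61854 0.304922 0.164469 0.843239 0.351912 0.457779 1.11468  1.8467
0.792117 0.154314 1.41639 0.433303  2.2147 0.149798 11.5196 0.415228 0.735567 5.94686 51.8478 0.0177902 0.518977 0.373874 0.388539 0.0227682
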