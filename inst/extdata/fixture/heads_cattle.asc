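ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.442871 0.0530917 0.194528  0.8428 0.0277665 0.356409 0.156149 0.0939692 0.541993 0.307235 0.0791571 0.413781 0.132073 0.698249 1.66211 0.78012
0.118847 0.659347 0.363695 0.53266 0.15767 0.0437613 0.0466757 0.00844521 1.01483 0.0279648 0.254108 0.408889 0.721753   6.844 2.22374 5.65609
0.096829 0.0587938 0.076264 0.0631764 0.453446 0.483134 0.67405 0.307141 0.362349 0.97147 1.60125 0.854627 0.24534 0.363062 2.38875 0.0523615
0.241952 0.587699 0.712079 0.614118 0.0784498 0.120919 0.0857159 0.493991 1.02513 0.0571059 0.987165 6.07997 0.782545 0.596822 1.17643 3.53605
 1.0771 0.270368 0.0593262 0.251076 0.325338 0.544572 0.330965  1.1115 0.194129 2.47652 1.92838 0.45142 0.0872997 0.0578021 0.257775 4.58353
0.429692 0.718039 0.986856 0.0160926 0.484125 0.181016 0.595975 0.0220134 1.28359 4.69092 9.39342 0.926694 2.84592 0.104111 0.216448 0.304937
0.392973 0.0435242 0.208433  1.1519 0.364919 1.16017 0.0231491 0.411507 0.237918 0.757047 0.293777 2.81359 0.444976 0.684994 3.43221 3.35649
0.771023 3.17311 0.054885 0.0381883 1.02882 1.85699 0.0887535 0.0317353 0.668296 0.153614 0.0400376 1.32377 0.411031  2.4839 1.14129 0.670974
0.337803 5.31895 0.691168 2.62474 0.0993206 2.63654 5.90597 0.31274 0.953025 3.89407 0.311653 6.56872 0.283906 0.0881282 0.368669 0.480352
0.61029 3.70348 1.88813 5.08997 0.814808 10.0708 0.206536 0.930284 0.311277 1.19223 0.0743111 1.20441 0.550054 0.632481 0.195795 0.395637
0.0577561 0.0477768 0.0452506 0.255534 0.0273559  3.9424 0.465299 0.0126166    4.69 0.286095 0.0475479 2.82621 1.42386 0.000894359 0.27202 0.0574224
 1.1343 0.108499 3.00633 0.513327 0.322579 1.12724 0.104225 0.872467 0.063599 0.124736 0.649318 3.22237 0.0834224 0.459277 0.233568 0.152028
0.359161 0.095974 0.163223 0.142991 3.94449 0.441429 0.346483 7.83851 0.752573 0.724648 0.655478 0.619542 0.158008 0.117404 0.566955 0.439611
4.89365 0.87387 0.105391 20.3326 0.866756 1.44506 1.34058 0.473615  3.0781 0.0110695 0.00880656 0.152583 0.247851 0.00993651 0.00199991 0.163045
 0.8134 6.78957 0.424486 2.63207 1.06864 1.01251 0.583864 0.98347 20.2052 4.53548 0.293203 0.383604 0.0431822 0.0930659 1.58276 1.94042
0.529277 0.114391 1.00822 0.154887 0.797691 0.124731 0.104436 1.15297 0.39962 2.17868 8.69206 0.00796968 0.350832 0.514582 0.407695 0.00821713
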