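ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
5.91256 5.57759 5.13815 6.05637 6.35677 7.15899 6.78705 6.74212 6.71179  6.8358 6.04019 4.97304 4.23325 4.61495 4.17008 3.80835
5.30619 5.34844 5.16688 6.38772 6.88755 7.82258 7.51109 7.58103 7.69891 7.86229 6.90085  5.9057 5.23248 5.53097 5.12754  4.6137
5.51578 5.43772 5.17055 6.09907 6.44417 7.28568 7.47605 7.67122  7.5064 7.81506 7.51008 6.74665 6.06011 5.98518  5.8173 5.62646
5.43951 5.45207 5.24637 6.13375 6.50321 7.32378 7.45757 7.55017 7.14776 7.48108 7.19606 6.45632 6.03181 6.24548 6.22907 6.40255
6.58764 6.68798 6.38937   6.974 7.21903 7.92729  7.7852 7.96198 7.62944  7.8973  7.7453 6.79348  6.5806 6.99381 6.64552 6.51073
6.87531 7.34654 6.97127 7.16202  7.3185 7.88318 8.01187 7.99095 7.65203 7.99923 8.13043 7.22714 7.22872 7.44905 7.45715 7.68577
7.68551 8.14814 7.97696 8.30173 8.07511 8.34411 8.42187 8.31462 8.42367 8.91418 9.18871 8.79185 9.29531 9.68771 10.0927 10.0481
8.21208  8.6347 8.49434 8.33522 7.99735 8.12703 8.41608 8.53428 8.78743 9.48904 9.90913 9.28966 9.57606 9.57693 9.84334 9.94867
10.1727 10.1387 10.2621 9.71947 9.28223 9.05049 9.19674 9.00807 9.48102 10.1534 10.5872 9.80577 10.2063  10.197 10.2974 10.4082
10.9691 10.8221 11.2367 11.0554 10.6383 10.5666 10.4874 10.2885 11.1809 11.6236  11.666 11.0892 11.3677  11.263 11.2317 11.1501
11.6194 11.3278 11.4626 11.0915 10.9626 10.8136 10.9784 11.1609  12.279 12.6548  13.087 12.6139 12.2775 12.3433 11.8638 11.6319
12.0821 11.6523 11.8406 11.6759 11.6336  11.254 11.4384 11.6427 12.7166 13.1788 13.6829 13.3614 12.6786 12.5258 12.3552 12.4219
12.8113 12.2647 12.2518 12.2485 12.2963 12.0869 12.6353 13.1255 14.2091  14.626 15.0721 14.9453 13.9344  13.921 13.3438 13.3072
 13.799 12.9462  12.759 12.7619 13.1962 12.7544 13.2153  13.725 15.0529 15.3414 15.7904 15.3802 14.1363   14.05 13.7478 13.7309
14.2772 13.9906 13.9447 14.1713 14.9656 14.8557 15.2406 15.0558 15.8449 16.2165  16.814 16.4493 15.4302 15.3022 15.0109 14.9763
13.9902 13.4012 12.6314 13.1609 14.6444 14.6364 15.0566  15.478 16.3268 16.7819  17.148 16.8216 16.2248 16.1152 16.2516 16.3429
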