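ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
229.396 276.608 206.738 192.325 248.977 328.347 251.385 203.222 214.485 218.207 375.527 328.205 301.294 301.883 263.272 284.564
232.423 264.532 208.983 264.557 208.836 281.744 186.658 199.169 147.684 197.382 220.311 270.716   264.2 279.608 259.353 300.789
352.209 319.885 293.688 288.608 279.821 252.629 235.508 215.231 201.116 243.868 372.404 368.513  333.36 451.859 391.084 359.919
275.388 288.677 223.585 200.927 298.491 263.457 185.626  160.75 177.726 284.597 261.736 239.427 224.112 322.311 304.418 365.891
270.705 266.649  207.59 215.761 252.042 257.842 182.818 216.099  203.18  267.18  271.35  246.49 189.312 279.546 274.634 345.491
274.293 193.006 192.635  161.28   201.9 253.534 235.075 159.699 153.137 198.251 232.487 213.993  163.67 195.031 204.127 225.854
395.276 322.051 250.801 307.086  297.27 295.171 253.895 164.775 164.799  204.19  211.47  131.67 140.429 151.485 170.505 218.405
299.289 262.731 240.321 199.799 296.631 246.122 215.154 190.417 264.343 295.261 230.267 195.353  160.55 173.974 172.907 149.022
271.023 209.899 254.304 251.027 219.325 226.568 181.323 198.642 257.767 250.139 187.171 168.055 189.173 204.315 226.588 176.895
220.287 175.593 221.839 205.279 201.569 265.812 207.906 152.903   198.6 178.885 143.047 156.144 139.945 126.599 180.401 177.923
158.447 151.361 158.022 191.786 171.751 192.893 175.946 193.472  203.23 311.158 180.215 242.023 185.999 141.459 182.427 115.841
173.786 197.478 209.787 269.838 188.547 211.669 229.652 192.748 237.792 228.361 197.632 240.709 198.997 170.317  188.27 128.845
191.803 198.079 226.126 214.312 206.501 253.279  344.73 258.914 350.493  447.01 306.582 354.855 297.693 271.581 273.493 204.164
114.568 134.462  197.13 160.467 163.796 173.371  216.55  261.47 389.792 403.561 445.331 643.849 481.858 423.364 473.405 232.072
 189.74 182.003 212.578 201.432 148.673 182.019 242.313 191.807  310.36 556.631 513.172 605.219 557.119 405.442 461.192 293.672
201.001 180.165 194.633 173.785 220.265 235.264 253.153 348.146 402.714 548.285 673.049 830.393 599.926 577.405 523.666 320.334
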