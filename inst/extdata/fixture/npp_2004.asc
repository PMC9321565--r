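ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
231.957  245.36 195.176 199.079 358.803 374.805 273.343 256.752 191.961 241.763 392.595 316.526 291.994 363.608 216.126 348.486
292.903  304.64 210.587 184.598 254.083 281.748  211.13 205.747 198.318 232.507 278.374 262.848 250.225 360.954 264.524  345.57
340.468 257.437 347.345 266.629 371.268 321.009 288.505 221.935 231.144 328.336 391.028 385.626 291.347 363.829 342.612 301.457
278.294 247.132 242.395 220.569  374.94 324.019 224.364 213.567 206.903 280.811 321.831 223.118 205.555 363.248 397.537 355.293
 275.99 248.807 199.271 217.486 229.689 315.423 201.771  215.85 199.953 278.765 304.373 238.781  197.37 283.725 285.878 410.158
289.591 252.606 195.173 205.727 184.074 255.238 179.172 209.064  190.55 242.661 272.162 192.101 145.219 204.926 169.536 232.351
 297.36 296.488 287.428 378.545 342.284 315.036 177.837 206.661  200.86 251.213 206.598 179.667  144.35 203.111 188.847 175.059
303.098 271.168 181.202 217.284 253.134 237.068 224.242 224.176  267.19  257.59 224.343 205.147 153.231 158.055 183.551  156.79
252.598  229.22 243.712 211.336 204.805 224.451 252.307 212.649 228.998 313.914 186.618 228.362 250.535 168.541 189.611 194.391
207.715 208.638 223.492 206.625 236.369 225.251  198.87 185.682 171.509 184.421 153.374 201.187 158.269  125.44 189.976 156.426
151.293  153.11 192.893 200.539 148.422 189.173 220.856 174.153 245.866 224.585 181.208  225.87 163.799 133.577 169.989 112.206
152.628 185.607 191.135  200.94 181.877 197.981 196.531 218.774 190.018 215.638 149.816 235.004 204.879 119.391 205.164 148.512
171.652 197.101 223.166 184.687 318.742 235.247 305.954 262.795 314.156  295.87 268.823 373.112 296.392 204.158 250.238 154.562
123.482 135.589 171.933 145.953 171.547 157.736 250.709 275.106 324.541 383.449 369.261 584.856 374.231 377.077 354.586 256.234
 170.67 161.676 181.911 193.686  203.52  166.44 245.825 224.921 321.186 448.414 411.914 755.051 597.946 424.262 528.113 244.397
131.706 201.054 176.556 164.746  191.28 198.626 318.691 342.621 396.731 404.247 515.949 635.973 587.789 435.563  447.97 266.757
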