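ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
 274.29 311.686   243.6 210.085 336.992 350.445 254.315 235.534 170.161 316.696 313.508 302.612 258.526 342.426 242.074 303.556
308.539 292.275  302.82 191.447 277.338 239.361  222.01  213.24 185.219 237.245 247.693 273.441 250.354 296.581 321.254 305.769
 357.23 313.914 243.236 283.328 315.244 321.017 355.472  234.93 222.918 219.062 379.975 408.041 389.967 407.564 299.144 390.019
300.813 254.227 209.032 239.505 280.345 309.854 261.926 233.336  195.31  234.69 355.583 289.635 246.895 316.658 304.869 451.797
298.628  222.17 189.207 213.177 283.604 335.362 235.306 241.242 223.473 293.688 263.147 220.554 184.792 245.241  295.77 328.429
328.461 184.257 241.271 185.733 213.913 272.648 184.622 186.641 238.537 174.346 226.121 194.789 170.367 215.705 190.817 275.112
391.899 276.734 304.502 309.323 267.486 334.432 185.863 198.311 217.203  196.28 213.204 177.583 141.321 184.356 190.821 186.766
289.542 249.141 231.738 245.245 233.386 271.342 194.057 211.488 253.741 241.129 214.943 203.192 153.782 194.239 187.148 200.664
229.284 205.086 258.682  193.07  245.05  216.92 229.412 175.859 300.505 240.079 219.008 210.095 192.333 210.894 196.431 130.175
234.275 261.884  247.65 184.199 238.286 216.047 202.587 169.814  229.63 184.101 172.563 191.504 145.254 142.316 186.664 160.054
158.393 158.311 193.938 210.618 142.245 222.216 192.221 184.444 241.607 231.567 189.132 211.516 225.477 156.688 148.766 105.915
193.769 202.371 207.437 224.746 200.477   200.9 207.196 180.257 200.244 210.567 182.294 236.554 191.111 154.561  203.25  115.58
185.282 162.311 205.232 208.417  223.63  234.85 324.312 256.599 255.607  326.47 271.879 377.792 346.573  222.15 300.368 191.163
124.813 160.569 178.094 196.247 173.066 173.295 263.357 240.862 293.305 391.574 350.033 512.865 484.182 393.755 399.093 239.396
162.857 160.882 217.694 138.909 159.618 153.811 199.455 211.675 299.194 458.114 462.127 697.643 466.888 464.155 617.083 314.888
 184.31  179.29 171.297 150.275 225.914 197.076 349.285 290.306 378.712 422.074 520.584 856.627 559.783 427.508 450.909 275.968
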