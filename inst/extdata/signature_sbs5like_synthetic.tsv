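context	probability
A[C>A]A	0.0089375
A[C>A]C	0.0073125
A[C>A]G	0.008125
A[C>A]T	0.008125
C[C>A]A	0.0061875
C[C>A]C	0.0050625
C[C>A]G	0.005625
C[C>A]T	0.005625
G[C>A]A	0.0055
G[C>A]C	0.0045
G[C>A]G	0.005
G[C>A]T	0.005
T[C>A]A	0.006875
T[C>A]C	0.005625
T[C>A]G	0.00625
T[C>A]T	0.00625
A[C>G]A	0.00439024
A[C>G]C	0.00439024
A[C>G]G	0.00439024
A[C>G]T	0.00439024
C[C>G]A	0.00329268
C[C>G]C	0.00329268
C[C>G]G	0.00329268
C[C>G]T	0.00329268
G[C>G]A	0.00329268
G[C>G]C	0.00329268
G[C>G]G	0.00329268
G[C>G]T	0.00329268
T[C>G]A	0.00402439
T[C>G]C	0.00402439
T[C>G]G	0.00402439
T[C>G]T	0.00402439
A[C>T]A	0.0146179
A[C>T]C	0.00584718
A[C>T]G	0.00584718
A[C>T]T	0.0146179
C[C>T]A	0.00502492
C[C>T]C	0.00200997
C[C>T]G	0.00200997
C[C>T]T	0.00502492
G[C>T]A	0.00502492
G[C>T]C	0.00200997
G[C>T]G	0.00200997
G[C>T]T	0.00502492
T[C>T]A	0.0146179
T[C>T]C	0.00584718
T[C>T]G	0.00584718
T[C>T]T	0.0146179
A[T>A]A	0.0061875
A[T>A]C	0.0061875
A[T>A]G	0.00680625
A[T>A]T	0.00556875
C[T>A]A	0.005625
C[T>A]C	0.005625
C[T>A]G	0.0061875
C[T>A]T	0.0050625
G[T>A]A	0.0050625
G[T>A]C	0.0050625
G[T>A]G	0.00556875
G[T>A]T	0.00455625
T[T>A]A	0.005625
T[T>A]C	0.005625
T[T>A]G	0.0061875
T[T>A]T	0.0050625
A[T>C]A	0.0719535
A[T>C]C	0.0411163
A[T>C]G	0.0513953
A[T>C]T	0.0411163
C[T>C]A	0.0338605
C[T>C]C	0.0193488
C[T>C]G	0.024186
C[T>C]T	0.0193488
G[T>C]A	0.0296279
G[T>C]C	0.0169302
G[T>C]G	0.0211628
G[T>C]T	0.0169302
T[T>C]A	0.0465581
T[T>C]C	0.0266047
T[T>C]G	0.0332558
T[T>C]T	0.0266047
A[T>G]A	0.00825
A[T>G]C	0.00675
A[T>G]G	0.0075
A[T>G]T	0.0075
C[T>G]A	0.00825
C[T>G]C	0.00675
C[T>G]G	0.0075
C[T>G]T	0.0075
G[T>G]A	0.00825
G[T>G]C	0.00675
G[T>G]G	0.0075
G[T>G]T	0.0075
T[T>G]A	0.00825
T[T>G]C	0.00675
T[T>G]G	0.0075
T[T>G]T	0.0075
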